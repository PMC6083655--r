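#' Dyadic relationship metrics
#'
#' Predictors of relationship quality between the two opponents of a
#' conflict: the asymmetry in the exchange of affiliative (AFFav) and
#' aggressive (AGGav) behaviours, David's scores from the direction and
#' frequency of submissive behaviours, and the dyadic rank distance
#' (difference of the opponents' David's scores).
#'
#' @name pcmc-relationship
NULL

#' Directed-behaviour asymmetry index
#'
#' For a dyad (aggressor a, victim v) and a behaviour class, with Ba->Bv
#' the count of behaviours a directed at v and Bv->Ba the reverse count,
#' \deqn{\mathrm{AFFav} = \frac{B_{a\to v}}{B_{a\leftrightarrow v}} -
#'       \frac{B_{v\to a}}{B_{a\leftrightarrow v}}}
#' where the denominator is the total exchanged. 0 means a symmetric
#' relationship, +1 that only the aggressor directs the behaviour, -1 the
#' reverse. With no exchanged behaviour the index is undefined and `NA`
#' is returned (downstream models drop such dyads).
#'
#' @param aggressor_to_victim,victim_to_aggressor nonnegative counts.
#' @return the index in `[-1, 1]`, or `NA_real_` when the total is 0.
#' @examples
#' asymmetry_index(3, 7)  # -0.4
#' @export
asymmetry_index <- function(aggressor_to_victim, victim_to_aggressor) {
  a <- as.numeric(aggressor_to_victim); v <- as.numeric(victim_to_aggressor)
  stopifnot(length(a) == length(v))
  if (any(a < 0 | v < 0, na.rm = TRUE)) stop("counts must be nonnegative", call. = FALSE)
  tot <- a + v
  out <- ifelse(tot > 0, (a - v) / tot, NA_real_)
  unname(out)
}

#' Per-dyad asymmetry indices from annotated focal events
#'
#' Counts directed behaviours of one registry category per ordered dyad
#' and evaluates [asymmetry_index()] for each unordered dyad, oriented as
#' (aggressor, victim) when a conflict table supplies roles, else by id
#' order.
#'
#' @param events annotated focal events (with `category` joined in).
#' @param category behaviour class: `"affiliative"` for AFFav,
#'   `"aggressive"` for AGGav.
#' @return data.frame `id_a, id_b, a_to_b, b_to_a, total, asymmetry`.
#' @export
dyad_asymmetries <- function(events, category = c("affiliative", "aggressive")) {
  category <- match.arg(category)
  ev <- events[!is.na(events$category) & events$category == category, , drop = FALSE]
  key_a <- pmin(ev$actor, ev$receiver)
  key_b <- pmax(ev$actor, ev$receiver)
  dyads <- unique(data.frame(id_a = key_a, id_b = key_b, stringsAsFactors = FALSE))
  if (nrow(dyads) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0), a_to_b = numeric(0),
                      b_to_a = numeric(0), total = numeric(0), asymmetry = numeric(0)))
  }
  dyads$a_to_b <- mapply(function(a, b) sum(ev$actor == a & ev$receiver == b), dyads$id_a, dyads$id_b)
  dyads$b_to_a <- mapply(function(a, b) sum(ev$actor == b & ev$receiver == a), dyads$id_a, dyads$id_b)
  dyads$total <- dyads$a_to_b + dyads$b_to_a
  dyads$asymmetry <- asymmetry_index(dyads$a_to_b, dyads$b_to_a)
  rownames(dyads) <- NULL
  dyads
}

#' Submission matrix from focal events
#'
#' Square win matrix for dominance scoring: entry (i, j) is the number of
#' submissive behaviours j directed at i, i.e. i's "wins" over j
#' (receiving submission counts as winning).
#'
#' @param events annotated focal events.
#' @param ids optional character vector fixing the matrix dimension and
#'   order; defaults to the sorted set of ids appearing in the events.
#' @return integer matrix with dimnames `ids` and zero diagonal.
#' @export
submission_matrix <- function(events, ids = NULL) {
  ev <- events[!is.na(events$category) & events$category == "submissive", , drop = FALSE]
  if (is.null(ids)) ids <- sort(unique(c(events$actor, events$receiver)))
  m <- matrix(0L, length(ids), length(ids), dimnames = list(winner = ids, loser = ids))
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      i <- ev$receiver[k]; j <- ev$actor[k]   # j submits to i
      if (i %in% ids && j %in% ids) m[i, j] <- m[i, j] + 1L
    }
  }
  m
}

#' David's scores from a win matrix
#'
#' For each pair with n(i,j) = wins(i,j) + wins(j,i) > 0 the win
#' proportion is P(i,j) = wins(i,j)/n(i,j); pairs that never interacted
#' contribute nothing. Then
#' \deqn{w_i = \sum_j P_{ij}, \quad w2_i = \sum_j P_{ij} w_j, \quad
#'       l_i = \sum_j P_{ji}, \quad l2_i = \sum_j P_{ji} l_j}
#' and \eqn{DS_i = w_i + w2_i - l_i - l2_i}. The scores of any matrix sum
#' to zero. `method = "Dij"` applies the dyadic sample-size correction
#' \eqn{D_{ij} = P_{ij} - (P_{ij} - 0.5)/(n_{ij} + 1)} before the sums.
#'
#' @param mat square numeric win matrix, zero diagonal, dimnames = ids.
#' @param method `"Pij"` (raw proportions, default) or `"Dij"`.
#' @return data.frame `id, w, w2, l, l2, ds`, sorted by decreasing `ds`.
#' @examples
#' m <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' davids_scores(m)
#' @export
davids_scores <- function(mat, method = c("Pij", "Dij")) {
  method <- match.arg(method)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) stop("win matrix must be square", call. = FALSE)
  if (any(diag(mat) != 0)) stop("win matrix must have a zero diagonal", call. = FALSE)
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  n <- mat + t(mat)
  P <- matrix(0, nrow(mat), ncol(mat))
  nz <- n > 0
  P[nz] <- mat[nz] / n[nz]
  if (method == "Dij") P[nz] <- P[nz] - (P[nz] - 0.5) / (n[nz] + 1)
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  out <- data.frame(id = ids, w = w, w2 = w2, l = l, l2 = l2,
                    ds = w + w2 - l - l2, stringsAsFactors = FALSE)
  out <- out[order(-out$ds), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dyadic rank distance from David's scores
#'
#' @param scores data.frame from [davids_scores()].
#' @param aggressor,victim individual ids.
#' @return list `signed` = DS(aggressor) - DS(victim), `absolute` =
#'   |signed|. Models consume the configured form (signed by default).
#' @export
rank_distance <- function(scores, aggressor, victim) {
  ia <- match(aggressor, scores$id); iv <- match(victim, scores$id)
  if (is.na(ia) || is.na(iv)) {
    stop("unknown id(s): ", paste(c(aggressor, victim)[c(is.na(ia), is.na(iv))], collapse = ", "),
         call. = FALSE)
  }
  s <- scores$ds[ia] - scores$ds[iv]
  list(signed = s, absolute = abs(s))
}

#' Filter PC-MC pairs by dyadic conflict involvement
#'
#' Retains only pairs whose (aggressor, victim) unordered dyad was
#' involved in at least `min_conflicts` conflicts — the usual guard
#' against basing conciliatory tendencies on dyads that almost never
#' fight.
#'
#' @param pairs data.frame with `aggressor` and `victim` columns (one row
#'   per PC-MC pair).
#' @param min_conflicts minimum conflicts per dyad (default 3).
#' @return the retained rows of `pairs`.
#' @export
dyad_conflict_filter <- function(pairs, min_conflicts = 3L) {
  stopifnot(min_conflicts >= 1L)
  key <- paste(pmin(pairs$aggressor, pairs$victim), pmax(pairs$aggressor, pairs$victim))
  keep <- key %in% names(which(table(key) >= min_conflicts))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
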