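threat:
  category: aggressive
  contact: false
  description: fixed stare with bared teeth and/or growl directed at the receiver
chase:
  category: aggressive
  contact: false
  description: running pursuit of the receiver
jaw_spar:
  category: aggressive
  contact: false
  description: open-mouth fencing without biting
snap:
  category: aggressive
  contact: false
  description: bite intention movement that does not connect
attack:
  category: aggressive
  contact: true
  description: lunge with physical contact
knock_down:
  category: aggressive
  contact: true
  description: forcing the receiver to the ground
stand_over:
  category: aggressive
  contact: true
  description: standing stiffly over the receiver with contact
pin:
  category: aggressive
  contact: true
  description: holding the receiver to the ground with the jaws or body
fight:
  category: aggressive
  contact: true
  description: mutual biting and wrestling
bite:
  category: aggressive
  contact: true
  description: closing the jaws on the receiver's body
stand_tall:
  category: dominant
  contact: false
  description: erect posture, raised tail and ears toward the receiver
ride_up:
  category: dominant
  contact: true
  description: placing forepaws on the receiver's back
crouch:
  category: submissive
  contact: false
  description: lowered body and tail, ears back, toward the receiver
tail_tuck:
  category: submissive
  contact: false
  description: tail tucked between the legs while oriented to the receiver
flee:
  category: submissive
  contact: false
  description: rapid withdrawal from the receiver
passive_submission:
  category: submissive
  contact: false
  description: lying on the back exposing the belly to the receiver
muzzle_lick_submissive:
  category: submissive
  contact: true
  description: crouched licking of the receiver's muzzle
approach_friendly:
  category: affiliative
  contact: false
  description: relaxed approach to within one body length of the receiver
stand_friendly:
  category: affiliative
  contact: false
  description: standing relaxed beside the receiver, no contact
play_bow:
  category: affiliative
  contact: false
  description: forequarters lowered, hindquarters up, soliciting play
nose_touch:
  category: affiliative
  contact: true
  description: brief nose-to-nose or nose-to-body contact
muzzle_lick:
  category: affiliative
  contact: true
  description: relaxed licking of the receiver's muzzle
body_rub:
  category: affiliative
  contact: true
  description: rubbing the body along the receiver
play_contact:
  category: affiliative
  contact: true
  description: relaxed wrestling or mouthing during play
close_proximity:
  category: proximity
  contact: false
  description: resting or standing within one body length of the receiver
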