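# Synthetic, illustrative guideline table in the national-recommendation
# style (first-choice / second-choice empiric regimens per sub-indication).
# It is NOT the published national guideline: it is a stand-in constructed
# for demonstrations and tests, consistent with common Dutch empiric
# practice (amoxicillin/ceftriaxone appropriate for CAP; nitrofurantoin
# for cystitis; ceftriaxone for complicated UTI; cefuroxime and
# amoxicillin-clavulanate inappropriate for CAP-m, cystitis and
# complicated UTI). Production audits must supply the current national
# table. Agents are ATC level-5 codes.
CAP:
  assessable: true
  first_choice:
    - [J01CA04]            # amoxicillin
  second_choice:
    - [J01DD04]            # ceftriaxone
    - [J01CE01]            # benzylpenicillin
CAP-m:
  assessable: true
  first_choice:
    - [J01CA04]            # amoxicillin
  second_choice:
    - [J01CE01]            # benzylpenicillin
    - [J01AA02]            # doxycycline
CAP-s:
  assessable: true
  first_choice:
    - [J01DD04, J01MA02]   # ceftriaxone + ciprofloxacin
    - [J01DD01, J01MA02]   # cefotaxime + ciprofloxacin
  second_choice:
    - [J01MA14]            # moxifloxacin
    - [J01CA04, J01MA02]   # amoxicillin + ciprofloxacin
HAP:
  assessable: true
  first_choice:
    - [J01DD04]            # ceftriaxone
  second_choice:
    - [J01CR05]            # piperacillin-tazobactam
COPD-exacerbation:
  assessable: true
  first_choice:
    - [J01CA04]            # amoxicillin
  second_choice:
    - [J01AA02]            # doxycycline
aspiration-pneumonia:
  assessable: true
  first_choice:
    - [J01CR02]            # amoxicillin-clavulanate
  second_choice:
    - [J01DD04, J01XD01]   # ceftriaxone + metronidazole
bronchitis:
  assessable: true
  first_choice:
    - [J01AA02]            # doxycycline
  second_choice:
    - [J01CA04]            # amoxicillin
other-RTI:
  assessable: false
  first_choice: []
  second_choice: []
cystitis:
  assessable: true
  first_choice:
    - [J01XE01]            # nitrofurantoin
  second_choice:
    - [J01XX01]            # fosfomycin
    - [J01EA01]            # trimethoprim
  route_constraint:
    J01XE01: oral
complicated-UTI:
  assessable: true
  first_choice:
    - [J01DD04]            # ceftriaxone
  second_choice:
    - [J01MA02]            # ciprofloxacin
    - [J01CA04, J01GB03]   # amoxicillin + gentamicin
chronic-prostatitis:
  assessable: true
  first_choice:
    - [J01MA02]            # ciprofloxacin
  second_choice:
    - [J01EE01]            # co-trimoxazole
other-UTI:
  assessable: false
  first_choice: []
  second_choice: []
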