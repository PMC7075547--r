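# Mapping between DHS birth-recode variable names and the childcap dialect.
# The childcap child-record table uses the names on the right; readers of raw
# DHS exports should rename columns according to this dictionary first.
b3: birth_cmc              # child date of birth, century-month code
v008: interview_cmc        # date of interview, century-month code
b5: alive                  # child alive at interview ("yes"/"no"; don't-know -> missing)
b7: age_at_death_months    # age at death in completed months (dead children only)
b4: child_sex              # "male"/"female"
v005: weight_raw           # woman's sample weight x 1,000,000 (DHS convention)
v133: mother_edu_years     # maternal education in single years
v012: mother_age_years     # mother's age at interview (15-49)
v101: unit1                # first-level administrative unit (region/province/state)
v190: wealth_quintile_provided   # DHS-provided wealth quintile (1-5), optional
v001: cluster_id
v002: household_id
caseid: mother_id
bidx: child_id             # birth index within the mother's history
v000: country
v007: survey_year
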