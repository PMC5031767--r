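condition,measure,mean,sd
white_prime,crime_relevant,28,6
white_prime,crime_irrelevant,24,6
no_prime,crime_relevant,24,6
no_prime,crime_irrelevant,24,6
black_prime,crime_relevant,20,6
black_prime,crime_irrelevant,24,6
# correlations
condition,measure_a,measure_b,correlation
white_prime,crime_relevant,crime_irrelevant,0.4
no_prime,crime_relevant,crime_irrelevant,0.4
black_prime,crime_relevant,crime_irrelevant,0.4
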