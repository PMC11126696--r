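# shortcuts to the exact-arithmetic internals exercised by the tests
mp_parse <- dnalie:::mp_parse
mp_format <- dnalie:::mp_format
mp_equal <- dnalie:::mp_equal
mp_is_zero <- dnalie:::mp_is_zero
mp_add <- dnalie:::mp_add
mp_sub <- dnalie:::mp_sub
mp_mul <- dnalie:::mp_mul
mp_pow <- dnalie:::mp_pow
mp_deriv <- dnalie:::mp_deriv
mp_eval <- dnalie:::mp_eval
mp_var <- dnalie:::mp_var
mp_const <- dnalie:::mp_const
mp_zero <- dnalie:::mp_zero
mp_one <- dnalie:::mp_one
mp_subst <- dnalie:::mp_subst
mp_vars <- dnalie:::mp_vars
rf <- dnalie:::rf
rf_format <- dnalie:::rf_format
rf_equal <- dnalie:::rf_equal
rf_is_zero <- dnalie:::rf_is_zero
rf_const <- dnalie:::rf_const
rf_zero <- dnalie:::rf_zero
rf_neg <- dnalie:::rf_neg
rf_eval <- dnalie:::rf_eval
rf_nullspace <- dnalie:::rf_nullspace
expr_to_ring <- dnalie:::expr_to_ring
expr_to_rf <- dnalie:::expr_to_rf
vf_equal <- dnalie:::vf_equal
vf_scale <- dnalie:::vf_scale
vf_in_basis <- dnalie:::vf_in_basis
prolong_characteristic <- dnalie:::prolong_characteristic
reduced_ode_format <- dnalie:::reduced_ode_format
wave_index_table <- dnalie:::wave_index_table
catalogue_cases <- dnalie:::catalogue_cases

# rational-coefficient structure constant expected from the commutator table
rf_of <- function(s) rf(mp_parse(s))
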