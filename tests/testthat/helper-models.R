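# Hand-solvable 5-reaction model: an uptake feeding two alternative
# conversion routes into a biomass precursor.
#
#   EX_A:      -> A      (uptake, ub 10)
#   R1:   A -> B         rule "g1 or g2"   (isoform pair)
#   R2:   A -> B         rule "g3 and g4"  (two-subunit complex)
#   R3:   B -> C         rule "g5"         (sole precursor step)
#   BIO:  C ->           objective
#
# Wild-type optimum: 10 (all flux through either route).
# By hand: deleting g1 or g2 leaves the other isoform (R1 on) -> viable;
# deleting g3 or g4 kills R2 but R1 carries the flux -> viable;
# deleting g5 closes the only path to C -> not viable;
# deleting both g1 and g2 closes R1 but R2 still runs -> viable;
# deleting g1, g2 and g3 closes both routes -> not viable.
toy_fba_model <- function() {
  S <- matrix(c(
    #EX_A R1  R2  R3 BIO
       1, -1, -1,  0,  0,   # A
       0,  1,  1, -1,  0,   # B
       0,  0,  0,  1, -1),  # C
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("EX_A", "R1", "R2", "R3", "BIO")))
  fba_model(S, lb = rep(0, 5), ub = c(10, 100, 100, 100, 100),
            objective = "BIO",
            rules = list(R1 = "g1 or g2", R2 = "g3 and g4", R3 = "g5"))
}

toy_expected_viability <- c(g1 = "viable", g2 = "viable", g3 = "viable",
                            g4 = "viable", g5 = "not_viable")
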