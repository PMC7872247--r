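# Small model builders shared across tests.

# A <-> B, single reversible reaction.
two_species_model <- function(kf = 1, Keq = 1, xA = 1, xB = 1) {
  mass_model(list(species("A", x0 = xA), species("B", x0 = xB)),
             list(reaction("R", c(A = 1), c(B = 1), kf = kf, Keq = Keq)))
}

# irreversible A -> B decay.
decay_model <- function(kf = 1, A0 = 1) {
  mass_model(list(species("A", x0 = A0), species("B", x0 = 0)),
             list(reaction("R", c(A = 1), c(B = 1), kf = kf,
                           reversible = FALSE)))
}

# enzyme cycle E + S <-> ES <-> E + P with fixed ligands.
enzyme_cycle_model <- function() {
  mass_model(
    list(species("E", x0 = 1e-6), species("ES", x0 = 1e-6),
         species("S", x0 = 1e-3, fixed = TRUE),
         species("P", x0 = 1e-4, fixed = TRUE)),
    list(reaction("bind", c(E = 1, S = 1), c(ES = 1), kf = 1e6, Keq = 1e3),
         reaction("cat", c(ES = 1), c(E = 1, P = 1), kf = 1e3, Keq = 1))
  )
}

# temp file under the session tempdir (removed with the session)
temp_path <- function(ext) tempfile(fileext = ext)

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), rel_tol)
}
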