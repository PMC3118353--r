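# Small deterministic fixtures shared across the suite.

chain3_net <- function() make_toy_network("chain", 3)

branch2_net <- function() make_toy_network("branch", 2)

# two parallel compressed chains: redundancy 2 when all four exchange
# fluxes are measured (the smallest system with a chi-square(2) test)
dof2_net <- function() {
  network_from_equations(paste0("r", 1:4),
                         c("S1_ext -> A", "A -> P1_ext",
                           "S2_ext -> B", "B -> P2_ext"))
}

# one uptake feeding two secretions; removing a flux-carrying branch breaks
# the balance of A
fork_net <- function() {
  network_from_equations(paste0("r", 1:3),
                         c("S_ext -> A", "A -> P_ext", "A -> Q_ext"))
}

# the 20-mode universe used by the recovery benchmarks: one substrate
# uptake, twenty secretion branches with distinct yields
branch20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- make_toy_network("branch", 20)
      cache <<- list(net = net, ems = enumerate_ems(net))
    }
    cache
  }
})

# two-layer route network: 9 elementary paths from one substrate to three
# products through three interchangeable intermediates. Projected onto the
# 4 external compounds the mode matrix has rank <= 4, so flux decompositions
# on compound-level exchange rates are highly non-unique -- the regime where
# a minimum-norm program spreads weight over many modes.
layered_net <- function() {
  yields <- matrix(c(2, 4, 6, 1, 3, 5, 3, 1, 2), 3, byrow = TRUE)
  eqs <- c("Glc_ext -> G", paste0("G -> M", 1:3))
  ids <- c("r0", paste0("rA", 1:3))
  for (i in 1:3) for (j in 1:3) {
    eqs <- c(eqs, sprintf("M%d -> %d P%d_ext", i, yields[i, j], j))
    ids <- c(ids, sprintf("rB%d%d", i, j))
  }
  network_from_equations(ids, eqs)
}

# project a reaction-level dataset onto external-compound exchange rates,
# mirroring exometabolome measurements (one rate per compound)
to_compound_rates <- function(ds, net, ems) {
  Sx <- S_ext(net)
  R_ext <- ds$R %*% t(Sx)
  colnames(R_ext) <- rownames(Sx)
  E_ext <- Sx %*% ems$E
  ems_ext <- elementary_mode_set(E_ext, fully_reversible = ems$fully_reversible)
  list(ds = list(X = ds$X, R = R_ext, scaling = ds$scaling), ems = ems_ext)
}

expect_ems_equal <- function(a, b) {
  expect_equal(a$n_modes, b$n_modes)
  expect_true(plpath:::ems_equal(a, b))
}
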