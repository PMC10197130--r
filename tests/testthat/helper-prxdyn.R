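## Shared fixtures for the test suite. Everything is built in code.

spin_std <- spin_interaction()

designs_std <- default_designs()
design_nerrd_r1 <- c(designs_std$nerrd, designs_std$r1)

## noise-free rate table of a single residue for a given motion under a
## condition list
rates_for <- function(model, conditions, err = 0.01, residue = "X",
                      spin = spin_std) {
  r <- vapply(conditions, function(cn) {
    if (cn$experiment == "R1") r1_rate(model, spin, cn)
    else r1rho_mas(model, spin, cn)
  }, numeric(1))
  rate_table(residue = rep(residue, length(conditions)), rate = r,
             rate_err = rep(err, length(conditions)),
             condition = vapply(conditions, condition_key, ""))
}

## small two-chain toy structure used by the structure metrics tests
toy_structure <- function(n = 12, displace = NULL) {
  mk_chain <- function(chain, xyz) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(chain = chain, resno = i, resid = "ALA",
                 elety = c("N", "CA", "C", "O"),
                 x = xyz[i, 1] + c(-1, 0, 1, 1.5),
                 y = xyz[i, 2] + c(0.2, 0, 0.3, 1.1),
                 z = xyz[i, 3] + c(-0.3, 0, 0.4, 0.1),
                 b = 20, occ = 1, stringsAsFactors = FALSE)))
  }
  base <- cbind(3 * cos(seq_len(n) * 0.7), 3 * sin(seq_len(n) * 0.7),
                0.8 * seq_len(n))
  xyz2 <- base
  if (!is.null(displace)) xyz2[displace$i, ] <- xyz2[displace$i, ] + displace$d
  structure_model(rbind(mk_chain("A", base), mk_chain("B", xyz2)))
}

## random rigid-body transform of the xyz columns of a structure's chain
rotate_chain <- function(s, chain, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  at <- s$atoms
  idx <- at$chain == chain
  at[idx, c("x", "y", "z")] <-
    as.matrix(at[idx, c("x", "y", "z")]) %*% t(R) +
    matrix(rep(runif(3, -5, 5), each = sum(idx)), ncol = 3)
  structure_model(at)
}

random_coil_fixture <- function() {
  utils::read.csv(system.file("extdata", "random_coil_ca_cb.csv",
                              package = "prxdyn"), stringsAsFactors = FALSE)
}
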