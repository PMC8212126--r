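# Shared fixtures: all data is generated in code, seeded.

# default toy conditions: two unequal compact domains (one bead per
# residue), optional flexible linker, synthetic profile with ~1%
# relative noise so chi^2 ~ 1 at the generating structure
toy_conditions <- function(seed = 42, linker = 0, M = 60) {
  spec <- two_domain_spec(seed = seed, beads = c(20, 12), radii = c(9, 7),
                          separation = 25, linker = linker)
  mol <- make_two_domain_system(spec)
  q <- seq(0.02, 0.3, length.out = M)
  prof <- simulate_profile(mol, q, noise = noise_spec(seed = seed + 1))
  list(spec = spec, mol = mol, q = q, prof = prof)
}

# small atomic molecule (random heavy-atom cloud) for forward-model tests
random_atomic_molecule <- function(n = 30, seed = 1, spread = 10) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05))
  atoms <- data.frame(element = elements, resid = seq_len(n),
                      resname = "GLY", atom = "CA", chain = "A",
                      stringsAsFactors = FALSE)
  saxs_molecule(atoms, matrix(stats::rnorm(3 * n, 0, spread), n, 3),
                rigid_group = rep(1L, n))
}

# independent O(N^2) double-loop Debye oracle over an explicit form-factor
# matrix (length(q) x n); shares no code with the package implementation
debye_oracle <- function(Fm, xyz, q) {
  n <- nrow(xyz)
  I <- numeric(length(q))
  for (k in seq_along(q)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        qd <- q[k] * d
        s <- if (qd < 1e-12) 1 else sin(qd) / qd
        acc <- acc + Fm[k, i] * Fm[k, j] * s
      }
    }
    I[k] <- acc
  }
  I
}

# adjusted Rand index between two labelings (independent of the SOM code)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# per-chain consecutive C-alpha (bead) distances in residue order
bead_chain_spacing <- function(mol) {
  ord <- order(mol$atoms$resid)
  sqrt(rowSums(diff(mol$xyz[ord, , drop = FALSE])^2))
}
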