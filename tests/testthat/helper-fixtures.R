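# fixture builders shared across test files; everything is generated in code

# write a minimal PDB file and return its path
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  # atoms: data.frame(serial, name, resid, x, y, z [Angstrom], element)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$serial, a$name, "ALA", "A", a$resid, a$x, a$y, a$z, 1.0, 0.0,
            a$element)
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# a CA-only frame with two "bundles" whose group COMs are planted a given
# distance apart along x
two_bundle_frame <- function(separation = 2.8, n_per_bundle = 4,
                             resid_a = 1:4, resid_b = 101:104) {
  posA <- cbind(rnorm(n_per_bundle, 0, 0.1), rnorm(n_per_bundle, 0, 0.1),
                rnorm(n_per_bundle, 0, 0.1))
  posA <- sweep(posA, 2, colMeans(posA))          # COM exactly at origin
  posB <- cbind(rnorm(n_per_bundle, 0, 0.1), rnorm(n_per_bundle, 0, 0.1),
                rnorm(n_per_bundle, 0, 0.1))
  posB <- sweep(posB, 2, colMeans(posB))
  posB[, 1] <- posB[, 1] + separation             # COM at (separation, 0, 0)
  synthetic_frame(rbind(posA, posB), resid = c(resid_a, resid_b))
}

random_cv_series <- function(n = 25, k = 3, seed = 1) {
  set.seed(seed)
  cv_series(paste0("cv", seq_len(k)), cumsum(runif(n, 0.5, 1.5)),
            matrix(rnorm(n * k) * 10^sample(-3:3, n * k, TRUE), n, k))
}

# rigid rotation matrix from an axis-angle
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
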