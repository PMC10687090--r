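# shared fixtures built in code

# small monomer/dimer bead pair tuned to the fully glycosylated Rg ratio
make_test_pair <- function(n_beads = 120, rg_m = 23.05, rg_d = 30.84,
                           seed = 11) {
  mono <- make_globule(n_beads, rg_m, seed = seed, label = "monomer")
  sep <- dimer_separation_for_ratio(mono, rg_d / rg_m)
  dimr <- suppressWarnings(make_dimer(mono, sep))
  list(monomer = mono, dimer = dimr)
}

# ideal Guinier decay I(q) = i0 * exp(-q^2 rg^2 / 3)
gaussian_curve <- function(rg, i0 = 1, q = seq(0.005, 0.2, length.out = 100),
                           sigma = 0.01) {
  scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3), rep(sigma, length(q)),
                   label = "gaussian")
}

# uniform-sphere form factor, radius R (Rg = sqrt(3/5) R)
sphere_curve <- function(R, q = seq(0.005, 0.3, length.out = 200)) {
  x <- q * R
  I <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  scattering_curve(q, I, pmax(I * 0.01, 1e-10), label = "sphere")
}

table1_concs <- c(0.27, 0.55, 1.07, 1.88, 4.37, 6.38, 7.51, 9.15)

# tiny aligned FASTA written to a temp file
write_test_msa <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i] %||% paste0("seq", i)), seqs[i]), con)
  close(con)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
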