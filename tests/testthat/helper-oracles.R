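# Independent oracles and shared fixtures. Oracles are deliberately naive
# re-derivations (full-matrix DP, exhaustive enumeration, direct pmf sums)
# kept separate from the implementation paths they check.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
random_nt <- function(n) paste(sample(DNA4, n, TRUE), collapse = "")

# full-matrix affine-gap local alignment score (triple-state DP, no
# traceback); gap of length L costs go + L * ge
sw_score_oracle <- function(a, b, smat, go, ge) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      s <- smat[av[i - 1], bv[j - 1]]
      v <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      M[i, j] <- max(v, 0)
      best <- max(best, M[i, j])
    }
  }
  best
}

# exhaustive best-chain total over all strictly collinear subsets of the
# blocks surviving the published filters
chain_total_oracle <- function(blocks, min_length = 200,
                               min_identity = 0.85) {
  surv <- blocks[blocks$length > min_length &
                   blocks$identity > min_identity, , drop = FALSE]
  nb <- nrow(surv)
  if (nb == 0) return(0)
  best <- 0
  extend <- function(last, total, remaining) {
    best <<- max(best, total)
    for (r in remaining) {
      ok <- is.null(last) ||
        (surv$qstart[r] >= surv$qend[last] &&
           surv$sstart[r] >= surv$send[last])
      if (ok) {
        extend(r, total + surv$length[r],
               remaining[remaining != r &
                           surv$qstart[remaining] >= surv$qstart[r]])
      }
    }
  }
  ord <- order(surv$qstart)
  surv <- surv[ord, , drop = FALSE]
  extend(NULL, 0, seq_len(nb))
  best
}

# exact upper-tail binomial by direct pmf summation
binom_upper_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# shared small scenarios, built once per test run
.fixtures <- new.env()
fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

noiseless_config <- function(seed = 21) {
  scenario_config(
    seed = seed,
    archetype_counts = c(I = 6, II = 4, III = 3, IV = 3),
    decoy_counts = c(hd_only = 4, lz_only = 4, redundant = 2),
    mutation_rate = 0,
    n_chromosomes = 6, n_scaffold_genes = 1, n_same_locus_pairs = 1,
    duplication_plan = tibble::tibble(
      subfamily = c("I", "II"), flank_identity = 1, span = 40000),
    expression_plan = list(
      samples = c("leaf", "stem", "ESR", "MSR", "LSR"),
      tissue_groups = list(root = c("ESR", "MSR", "LSR")),
      class_counts = c(constitutive = 6, non_expressed = 3,
                       tissue_specific = 4, partial = 3),
      noise_sd = 0, leaf_changed = 5, root_changed = 6, change_ratio = 8),
    qpcr_plan = list(n_targets = 4, timepoints = c("NTC", "5h", "15h"),
                     ratios = c(1, 4, 0.25), ct_sd = 0,
                     baseline_ct = 24, reference_ct = 18)
  )
}

noiseless_scenario <- function() {
  fixture("noiseless_scn", function() generate_scenario(noiseless_config()))
}
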