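# Conserved-motif discovery by ZOOPS expectation-maximization: each
# sequence contributes zero or one site; motifs are found one at a time,
# masking the sites of each accepted motif before searching for the next.

#' Discover conserved protein motifs by ZOOPS EM
#'
#' For each motif in turn, EM is run from several seeded starts at every
#' candidate width; the (width, start) combination maximizing information
#' content per column is kept, its sites are masked, and the search repeats
#' until `max_motifs` motifs are found or the best information content per
#' column falls below `ic_floor`.
#'
#' The ZOOPS model: a sequence of length `L` contains one motif site at a
#' uniformly chosen position with probability `gamma`, otherwise none;
#' non-site positions follow a 0-order background estimated from the data.
#' The EM objective (the observed-data log likelihood penalized by the
#' Dirichlet smoothing term that matches the M-step pseudocounts) is
#' non-decreasing across iterations.
#'
#' @param sequences Named character vector of protein sequences (>= 2), or
#'   an `AAStringSet`.
#' @param widths Candidate motif widths within 11..50
#'   (default the coarse grid `c(11, 15, 21, 29, 41, 50)`).
#' @param max_motifs Maximum number of motifs (default 15).
#' @param seed Integer seed controlling the EM starts.
#' @param n_starts Seeded EM starts per width (default 10); each start is
#'   ranked by a short EM run and the best are iterated to convergence.
#' @param max_iter EM iteration cap per start (default 50).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param ic_floor Stop when the best motif's information content per
#'   column drops below this many bits (default 0.5).
#' @return List of `hdz_motif` objects; each has `motif_id`, `width`,
#'   `pwm` (20 x width column-stochastic matrix), `sites` (tibble
#'   `seq_id`, `offset` 0-based), `information_content` (total bits),
#'   `ic_per_column`, `log_likelihood`, `ll_trace`.
#' @export
discover_motifs <- function(sequences, widths = c(11, 15, 21, 29, 41, 50),
                            max_motifs = 15, seed = 1, n_starts = 10,
                            max_iter = 50, tol = 1e-6, ic_floor = 0.5) {
  sequences <- as_named_character(sequences)
  if (length(sequences) < 2) abort("need >= 2 sequences")
  if (any(widths < 11 | widths > 50)) {
    abort("motif widths must lie within 11..50")
  }
  enc <- lapply(sequences, encode_aa)
  masks <- lapply(enc, function(e) rep(FALSE, length(e)))
  motifs <- list()
  for (m in seq_len(max_motifs)) {
    best <- NULL
    for (w in widths) {
      if (w > max(lengths(enc))) {
        warn(sprintf("width %d exceeds the longest sequence; skipped", w))
        next
      }
      # rank many seeded starts by a short EM run, then iterate the most
      # promising ones to convergence (guards against phase-shifted
      # local optima)
      short <- list()
      for (s in seq_len(n_starts)) {
        fit <- zoops_em(enc, masks, w,
                        seed = child_seed(seed, m * 1000L + w * 10L + s),
                        max_iter = 3L, tol = tol)
        if (!is.null(fit)) short[[length(short) + 1]] <-
          list(seed = child_seed(seed, m * 1000L + w * 10L + s),
               obj = fit$log_likelihood)
      }
      if (length(short) == 0) next
      objs <- vapply(short, function(x) x$obj, numeric(1))
      top <- order(objs, decreasing = TRUE)[seq_len(min(2, length(short)))]
      for (s in top) {
        fit <- zoops_em(enc, masks, w, seed = short[[s]]$seed,
                        max_iter = max_iter, tol = tol)
        if (is.null(fit)) next
        fit <- phase_refine(fit, enc, masks, w, max_iter = max_iter,
                            tol = tol)
        if (is.null(best) || fit$ic_per_column > best$ic_per_column) {
          best <- fit
        }
      }
    }
    if (is.null(best) || best$ic_per_column < ic_floor) break
    best$motif_id <- m
    motifs[[m]] <- structure(best, class = "hdz_motif")
    # mask accepted sites before the next round
    for (r in seq_len(nrow(best$sites))) {
      id <- best$sites$seq_id[r]
      off <- best$sites$offset[r]
      masks[[id]][(off + 1):(off + best$width)] <- TRUE
    }
  }
  motifs
}

# One EM run: integer-encoded sequences, per-position masks, fixed width.
# Returns NULL when no sequence admits a window of this width.
zoops_em <- function(enc, masks, w, seed = 1, max_iter = 50, tol = 1e-6,
                     init_pwm = NULL) {
  n <- length(enc)
  # windows not overlapping any masked position
  allowed <- purrr::map2(enc, masks, function(e, mk) {
    nw <- length(e) - w + 1
    if (nw < 1) return(integer(0))
    ok <- !vapply(seq_len(nw), function(i) any(mk[i:(i + w - 1)]),
                  logical(1))
    which(ok)
  })
  if (all(lengths(allowed) == 0)) return(NULL)
  # background from unmasked residues
  all_res <- unlist(purrr::map2(enc, masks, function(e, mk) e[!mk]))
  bg <- (tabulate(all_res + 1L, nbins = 20) + 1) / (length(all_res) + 20)
  if (is.null(init_pwm)) {
    # seeded start: PWM from a random allowed window, softened
    start <- with_seed(seed, {
      cand <- which(lengths(allowed) > 0)
      si <- sample(cand, 1)
      off <- sample(allowed[[si]], 1)
      list(si = si, off = off)
    })
    site <- enc[[start$si]][start$off:(start$off + w - 1)]
    pwm <- matrix(rep(bg, w), nrow = 20)
    for (j in seq_len(w)) {
      pwm[, j] <- 0.3 * pwm[, j]
      pwm[site[j] + 1L, j] <- pwm[site[j] + 1L, j] + 0.7
    }
  } else {
    pwm <- init_pwm
  }
  gamma <- 0.5
  log_bg <- log(bg)
  prev_ll <- -Inf
  ll_trace <- numeric(0)
  z <- vector("list", n)
  for (iter in seq_len(max_iter)) {
    logratio <- log(pwm) - matrix(log_bg, 20, w)
    ll <- 0
    for (i in seq_len(n)) {
      ai <- allowed[[i]]
      bg_ll <- sum(log_bg[enc[[i]] + 1L])
      if (length(ai) == 0) {
        z[[i]] <- numeric(0)
        ll <- ll + bg_ll
        next
      }
      sc <- cpp_window_scores(enc[[i]], logratio)[ai]
      m_i <- length(ai)
      # log joint of (site at ai[j]) and (no site)
      l_site <- log(gamma / m_i) + bg_ll + sc
      l_none <- log(1 - gamma) + bg_ll
      mx <- max(c(l_site, l_none))
      denom <- sum(exp(c(l_site, l_none) - mx))
      ll <- ll + mx + log(denom)
      z[[i]] <- exp(l_site - mx) / denom
    }
    # EM objective: observed log likelihood plus the Dirichlet smoothing
    # term matching the M-step pseudocounts (MAP-EM is monotone in this
    # penalized objective, not in the raw likelihood)
    obj <- ll + 0.1 * sum(log(pwm))
    ll_trace <- c(ll_trace, obj)
    if (is.finite(prev_ll) && (obj - prev_ll) < tol * abs(prev_ll)) break
    prev_ll <- obj
    # M-step
    counts <- matrix(0.1, 20, w) # pseudocounts
    ztot <- 0
    for (i in seq_len(n)) {
      ai <- allowed[[i]]
      if (length(ai) == 0) next
      zi <- z[[i]]
      ztot <- ztot + sum(zi)
      keep <- which(zi > 1e-8)
      for (jj in keep) {
        off <- ai[jj]
        site <- enc[[i]][off:(off + w - 1)]
        for (p in seq_len(w)) {
          counts[site[p] + 1L, p] <- counts[site[p] + 1L, p] + zi[jj]
        }
      }
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(ztot / n, 1e-4), 1 - 1e-4)
  }
  # hard site calls: argmax posterior when P(site) > 0.5
  sites <- purrr::map(seq_len(n), function(i) {
    ai <- allowed[[i]]
    if (length(ai) == 0 || sum(z[[i]]) <= 0.5) return(NULL)
    tibble(seq_id = i, offset = ai[which.max(z[[i]])] - 1L)
  }) |> bind_rows()
  ic <- motif_ic(pwm, bg)
  list(width = w, pwm = pwm, sites = sites,
       information_content = ic, ic_per_column = ic / w,
       log_likelihood = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       background = bg)
}

# Phase-shift refinement: EM's classic failure mode on planted motifs is
# convergence to a frame shifted by a few columns. Rebuild the PWM from the
# current hard sites shifted by s, rerun EM, and keep any shift that
# improves the objective; repeat until no shift helps.
phase_refine <- function(fit, enc, masks, w, max_iter, tol,
                         shifts = c(-5:-1, 1:5), rounds = 4) {
  for (round in seq_len(rounds)) {
    improved <- FALSE
    for (s in shifts) {
      sites <- fit$sites
      if (nrow(sites) < 2) return(fit)
      offs <- sites$offset + s
      ok <- vapply(seq_len(nrow(sites)), function(r) {
        i <- sites$seq_id[r]
        offs[r] >= 0 && offs[r] + w <= length(enc[[i]]) &&
          !any(masks[[i]][(offs[r] + 1):(offs[r] + w)])
      }, logical(1))
      if (sum(ok) < 2) next
      counts <- matrix(0.5, 20, w)
      for (r in which(ok)) {
        site <- enc[[sites$seq_id[r]]][(offs[r] + 1):(offs[r] + w)]
        for (p in seq_len(w)) {
          counts[site[p] + 1L, p] <- counts[site[p] + 1L, p] + 1
        }
      }
      init <- sweep(counts, 2, colSums(counts), "/")
      cand <- zoops_em(enc, masks, w, max_iter = max_iter, tol = tol,
                       init_pwm = init)
      if (!is.null(cand) &&
          cand$log_likelihood > fit$log_likelihood + 1e-9) {
        fit <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  fit
}

motif_ic <- function(pwm, bg) {
  sum(pwm * (log2(pmax(pwm, 1e-12)) - matrix(log2(bg), nrow(pwm),
                                             ncol(pwm))))
}

#' @export
print.hdz_motif <- function(x, ...) {
  cat(sprintf("<hdz_motif %s> width %d, %d sites, %.2f bits/column\n",
              x$motif_id, x$width, nrow(x$sites), x$ic_per_column))
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a motif
#'
#' @param motif An `hdz_motif`.
#' @return Character scalar of per-column argmax residues.
#' @export
motif_consensus <- function(motif) {
  paste(AA_ALPHABET[apply(motif$pwm, 2, which.max)], collapse = "")
}

#' Tidy a motif into one row per position/residue
#'
#' @param x An `hdz_motif`.
#' @param ... Unused.
#' @return Tibble `position`, `residue`, `probability`.
#' @export
tidy.hdz_motif <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 20),
    residue = rep(AA_ALPHABET, x$width),
    probability = as.vector(x$pwm)
  )
}

#' One-row summary of a motif fit
#'
#' @param x An `hdz_motif`.
#' @param ... Unused.
#' @return Tibble `motif_id`, `width`, `n_sites`, `information_content`,
#'   `ic_per_column`, `log_likelihood`.
#' @export
glance.hdz_motif <- function(x, ...) {
  tibble(motif_id = x$motif_id, width = x$width, n_sites = nrow(x$sites),
         information_content = x$information_content,
         ic_per_column = x$ic_per_column,
         log_likelihood = x$log_likelihood)
}

#' Export motifs in MEME-minimal text format
#'
#' Writes the letter-probability matrices plus a companion site TSV.
#'
#' @param motifs List of `hdz_motif` objects.
#' @param sequences The sequences they were discovered in (for site ids).
#' @param path Output text file; sites go to `paste0(path, ".sites.tsv")`.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, sequences, path) {
  sequences <- as_named_character(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""),
             con)
  sites <- list()
  for (mo in motifs) {
    writeLines(sprintf("MOTIF motif_%d %s", mo$motif_id,
                       motif_consensus(mo)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
      mo$width, nrow(mo$sites)), con)
    # MEME orders columns alphabetically
    ord <- order(AA_ALPHABET)
    for (j in seq_len(mo$width)) {
      writeLines(paste(sprintf("%.6f", mo$pwm[ord, j]), collapse = " "),
                 con)
    }
    writeLines("", con)
    sites[[length(sites) + 1]] <- mutate(
      mo$sites, motif_id = mo$motif_id,
      seq_name = names(sequences)[.data$seq_id]
    )
  }
  readr::write_tsv(bind_rows(sites), paste0(path, ".sites.tsv"))
  invisible(path)
}
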