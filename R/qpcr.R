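# qPCR relative quantification (2^-ddCt) and Duncan's multiple range test.

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` within each sample;
#' `ddCt = dCt_sample - dCt_calibrator`; relative expression is
#' `2^(-ddCt)`. A sample whose dCt equals the calibrator's is exactly 1,
#' and adding any constant to every Ct leaves the result unchanged.
#'
#' @param target_ct,ref_ct Ct replicates of target and reference gene in
#'   the sample of interest.
#' @param calibrator_target_ct,calibrator_ref_ct Ct replicates in the
#'   calibrator (e.g. the no-treatment control).
#' @return Relative expression (positive scalar).
#' @export
#' @examples
#' ddct(c(20, 20), c(18, 18), c(22, 22), c(18, 18)) # 4
ddct <- function(target_ct, ref_ct, calibrator_target_ct,
                 calibrator_ref_ct) {
  for (v in list(target_ct, ref_ct, calibrator_target_ct,
                 calibrator_ref_ct)) {
    if (length(v) == 0) abort("all replicate sets must be nonempty")
  }
  dct <- mean(target_ct) - mean(ref_ct)
  dct_cal <- mean(calibrator_target_ct) - mean(calibrator_ref_ct)
  2^(-(dct - dct_cal))
}

#' Analyze a qPCR Ct table
#'
#' For every target gene and sample, computes per-replicate dCt values
#' (replicate `r` of the target paired with replicate `r` of the
#' reference), converts them to per-replicate relative expression against
#' the calibrator sample's mean dCt, and letters the samples by Duncan's
#' multiple range test on the per-replicate relative expressions.
#'
#' @param ct Tibble as from [read_ct_table()]: `sample`, `target`,
#'   `reference`, `replicate`, `ct`.
#' @param calibrator Sample label used as calibrator (default `"NTC"`).
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @return An `hdz_qpcr` tibble: `target`, `sample`, `relative_expression`
#'   (mean across replicates), `sd`, `letter` (per-target Duncan groups;
#'   the calibrator's mean is 1 by construction).
#' @export
qpcr_analysis <- function(ct, calibrator = "NTC", alpha = 0.05) {
  need <- c("sample", "target", "reference", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(sprintf("ct table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  ref_gene <- unique(ct$reference)
  if (length(ref_gene) != 1) abort("expected a single reference gene")
  targets <- setdiff(unique(ct$target), ref_gene)
  out <- purrr::map(targets, function(tg) {
    sub <- filter(ct, .data$target == tg)
    refs <- filter(ct, .data$target == ref_gene)
    # per-sample, per-replicate dCt
    dct <- left_join(
      select(sub, "sample", "replicate", target_ct = "ct"),
      select(refs, "sample", "replicate", ref_ct = "ct"),
      by = c("sample", "replicate")
    ) |>
      mutate(dct = .data$target_ct - .data$ref_ct)
    if (anyNA(dct$ref_ct)) {
      abort(sprintf("missing reference Ct replicates for target '%s'", tg))
    }
    cal <- filter(dct, .data$sample == calibrator)
    if (nrow(cal) == 0) {
      abort(sprintf("calibrator sample '%s' absent for target '%s'",
                    calibrator, tg))
    }
    dct <- mutate(dct, rel = 2^(-(.data$dct - mean(cal$dct))))
    groups <- dct |>
      group_by(.data$sample) |>
      summarise(values = list(.data$rel), .groups = "drop")
    letters_tbl <- duncan_mrt(
      setNames(groups$values, groups$sample), alpha = alpha)
    dct |>
      group_by(.data$sample) |>
      summarise(relative_expression = mean(.data$rel),
                sd = stats::sd(.data$rel), .groups = "drop") |>
      left_join(select(letters_tbl, "label", "letter"),
                by = c(sample = "label")) |>
      mutate(target = tg) |>
      select("target", "sample", "relative_expression", "sd", "letter")
  }) |> bind_rows()
  class(out) <- c("hdz_qpcr", class(out))
  out
}

#' Duncan's multiple range test letter grouping
#'
#' One-way balanced design: the pooled error mean square is the average
#' within-group variance; means are sorted and a range spanning `p` means
#' is significant when it exceeds the least significant range
#' `R_p = q_p * sqrt(MSE / n)`, where `q_p` is the studentized-range
#' quantile at Duncan's protection level `alpha_p = 1 - (1 - alpha)^(p-1)`
#' (see [duncan_critical_q()]). Letters are assigned so that two groups
#' share a letter exactly when their span is not significant; groups are
#' contiguous in mean order.
#'
#' @param groups Named list of replicate value vectors (>= 2 groups, each
#'   with the same number >= 2 of replicates), or a two-column data frame
#'   `label`, `value`.
#' @param alpha Significance level (default 0.05).
#' @return An `hdz_duncan` tibble: `label`, `mean`, `n`, `letter`,
#'   ordered by decreasing mean; attributes `mse`, `df_error`, `alpha`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$label)
  }
  k <- length(groups)
  if (k < 2) abort("need >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2)) abort("each group needs >= 2 replicates")
  if (length(unique(ns)) != 1) {
    abort("unbalanced designs are not supported (unequal replicate counts)")
  }
  n <- ns[1]
  means <- vapply(groups, mean, numeric(1))
  mse <- mean(vapply(groups, stats::var, numeric(1)))
  df_error <- k * (n - 1)
  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  # critical ranges per span p = 2..k
  rp <- c(NA_real_, vapply(2:k, function(p) {
    duncan_critical_q(alpha, p, df_error) * sqrt(mse / n)
  }, numeric(1)))
  # maximal non-significant stretches: from each start, extend while the
  # spanned range stays below its critical value
  covered <- rep(FALSE, k)
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      span <- j + 1 - i + 1
      d <- sorted[i] - sorted[j + 1]
      # share a letter when the span is below its critical range; exact
      # ties (d = 0) always share, covering the zero-variance null case
      if (d < rp[span] - 1e-12 || d <= 1e-12) j <- j + 1
      else break
    }
    if (length(stretches) == 0 ||
        j > stretches[[length(stretches)]][2]) {
      stretches[[length(stretches) + 1]] <- c(i, j)
      covered[i:j] <- TRUE
    }
  }
  lab <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    lab[rng[1]:rng[2]] <- paste0(lab[rng[1]:rng[2]], letters[s])
  }
  out <- tibble(
    label = names(sorted), mean = unname(sorted), n = as.integer(n),
    letter = lab
  )
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_error
  attr(out, "alpha") <- alpha
  class(out) <- c("hdz_duncan", class(out))
  out
}

#' Duncan's protected studentized-range quantile
#'
#' `q` such that the studentized range of `p` means with `df` error
#' degrees of freedom exceeds it with probability
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` (Duncan's protection level).
#' Strictly increasing in `p` and decreasing in `df`; matches the
#' published Duncan significant-range tables.
#'
#' @param alpha Nominal per-comparison level.
#' @param p Number of means spanned (>= 2).
#' @param df Error degrees of freedom.
#' @return The critical studentized range.
#' @export
#' @examples
#' round(duncan_critical_q(0.05, 2, 6), 2) # 3.46
duncan_critical_q <- function(alpha, p, df) {
  qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Tidy a Duncan letter grouping
#'
#' @param x An `hdz_duncan` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.hdz_duncan <- function(x, ...) {
  tibble(label = x$label, mean = x$mean, n = x$n, letter = x$letter)
}

#' One-row model summary of a Duncan test
#'
#' @param x An `hdz_duncan` object.
#' @param ... Unused.
#' @return Tibble `n_groups`, `mse`, `df_error`, `alpha`.
#' @export
glance.hdz_duncan <- function(x, ...) {
  tibble(n_groups = nrow(x), mse = attr(x, "mse"),
         df_error = attr(x, "df_error"), alpha = attr(x, "alpha"))
}

#' Plot qPCR relative expression with Duncan letters
#'
#' @param object An `hdz_qpcr` tibble from [qpcr_analysis()].
#' @param ... Unused.
#' @return A ggplot object (bars +/- sd, letters above).
#' @export
autoplot.hdz_qpcr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample,
                                       y = .data$relative_expression)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$relative_expression - .data$sd,
      ymax = .data$relative_expression + .data$sd), width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      y = .data$relative_expression + .data$sd,
      label = .data$letter), vjust = -0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)")
}
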