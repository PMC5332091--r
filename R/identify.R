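# Family identification: dual-domain profile evidence, redundancy removal,
# and protein physico-chemical properties.

#' Identify HD-Zip family members in a proteome
#'
#' A protein is retained when both the homeodomain and the leucine-zipper
#' profile score with `evalue < evalue_threshold`, both window scores are
#' positive in log-odds terms (`score > min_bits`; an empirical E-value
#' has granularity `1 / (null_shuffles + 1)`, so a deeply negative score
#' can tie the E-value floor by chance -- the bit-score requirement
#' rejects those), and the sequence is not redundant with an
#' already-retained protein (first occurrence in input order wins). Every
#' rejection carries a reason: `missing_HD`, `missing_LZ`, `low_score` or
#' `redundant`.
#'
#' @param proteome Named character vector of protein sequences, an
#'   `AAStringSet`, or a FASTA path.
#' @param profiles Named list with at least `HD` and `LZ` profiles
#'   (default [default_profiles()]).
#' @param evalue_threshold Retention threshold on both domains
#'   (default 0.01).
#' @param min_bits Minimum per-domain log-odds score in bits (default 0).
#' @param identity_threshold Redundancy rule: 1.0 (default) removes exact
#'   sequence duplicates only; values below 1 remove any later sequence
#'   whose best local alignment to a retained sequence covers the shorter
#'   sequence at at least this identity.
#' @param null_shuffles,seed Passed to [scan_profile()].
#' @return Tibble with one row per protein: `protein_id`, `retained`,
#'   `HD_score`, `HD_evalue`, `LZ_score`, `LZ_evalue`, `reason` (NA when
#'   retained), `length_aa`, `mw_da`, `pi`.
#' @export
identify_family <- function(proteome, profiles = default_profiles(),
                            evalue_threshold = 0.01, min_bits = 0,
                            identity_threshold = 1.0,
                            null_shuffles = 199, seed = 1) {
  if (is.character(proteome) && length(proteome) == 1 &&
      is.null(names(proteome)) && file.exists(proteome)) {
    proteome <- read_proteome(proteome)
  }
  proteome <- as_named_character(proteome)
  if (!all(c("HD", "LZ") %in% names(profiles))) {
    abort("profiles must include both 'HD' and 'LZ'")
  }
  if (length(proteome) == 0) {
    return(tibble(
      protein_id = character(), retained = logical(),
      HD_score = double(), HD_evalue = double(),
      LZ_score = double(), LZ_evalue = double(),
      reason = character(), length_aa = integer(),
      mw_da = double(), pi = double()
    ))
  }
  retained_seqs <- character(0)
  rows <- vector("list", length(proteome))
  for (i in seq_along(proteome)) {
    id <- names(proteome)[i]
    seq <- proteome[[i]]
    hd <- scan_profile(seq, profiles$HD, null_shuffles = null_shuffles,
                       seed = child_seed(seed, i * 2L), protein_id = id)
    lz <- scan_profile(seq, profiles$LZ, null_shuffles = null_shuffles,
                       seed = child_seed(seed, i * 2L + 1L), protein_id = id)
    has_hd <- hd$evalue < evalue_threshold
    has_lz <- lz$evalue < evalue_threshold
    reason <- NA_character_
    retained <- FALSE
    if (!has_hd) {
      reason <- "missing_HD"
    } else if (!has_lz) {
      reason <- "missing_LZ"
    } else if (hd$score <= min_bits || lz$score <= min_bits) {
      reason <- "low_score"
    } else if (is_redundant(seq, retained_seqs, identity_threshold)) {
      reason <- "redundant"
    } else {
      retained <- TRUE
      retained_seqs <- c(retained_seqs, seq)
    }
    props <- protein_properties(seq)
    rows[[i]] <- tibble(
      protein_id = id, retained = retained,
      HD_score = hd$score, HD_evalue = hd$evalue,
      LZ_score = lz$score, LZ_evalue = lz$evalue,
      reason = reason, length_aa = nchar(seq),
      mw_da = props$molecular_weight, pi = props$isoelectric_point
    )
  }
  bind_rows(rows)
}

is_redundant <- function(seq, retained_seqs, identity_threshold) {
  if (length(retained_seqs) == 0) return(FALSE)
  if (identity_threshold >= 1.0) return(seq %in% retained_seqs)
  scheme <- scoring_scheme("protein")
  for (r in retained_seqs) {
    blk <- smith_waterman(seq, r, scheme)
    shorter <- min(nchar(seq), nchar(r))
    if (blk$length > 0 &&
        (blk$matches / shorter) >= identity_threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' Molecular weight and isoelectric point of a protein
#'
#' Molecular weight sums average residue masses plus one water; the
#' isoelectric point is the pH at which the Henderson--Hasselbalch net
#' charge over the free termini and ionizable side chains (packaged
#' Bjellqvist-style pK set) crosses zero, located by bisection to
#' `|charge| < 1e-4`.
#'
#' @param sequence Amino-acid sequence over the 20 standard residues.
#' @return List with `molecular_weight` (Da) and `isoelectric_point` (pH;
#'   `NA` for the empty sequence).
#' @export
#' @examples
#' protein_properties("G")$molecular_weight # 75.07
protein_properties <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("non-standard residue '%s' at position %d",
                  chars[bad[1]], bad[1]))
  }
  if (length(chars) == 0) {
    return(list(molecular_weight = 0, isoelectric_point = NA_real_))
  }
  mw <- sum(AA_MASS[chars]) + WATER_MASS
  counts <- table(factor(chars, levels = AA_ALPHABET))
  charge_at <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PK_TABLE$nterm))
    neg <- 1 / (1 + 10^(PK_TABLE$cterm - ph))
    for (res in names(PK_TABLE$basic)) {
      pos <- pos + counts[[res]] / (1 + 10^(ph - PK_TABLE$basic[[res]]))
    }
    for (res in names(PK_TABLE$acidic)) {
      neg <- neg + counts[[res]] / (1 + 10^(PK_TABLE$acidic[[res]] - ph))
    }
    pos - neg
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- charge_at(mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(molecular_weight = mw, isoelectric_point = mid)
}
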