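# Shared local-alignment engine: exact affine-gap Smith-Waterman for short
# sequences and k-mer seed-and-extend for 100-kb nucleotide flanks.

#' Create a local-alignment scoring scheme
#'
#' @param mode `"nucleotide"` (match/mismatch integers) or `"protein"`
#'   (BLOSUM62 substitution matrix from Biostrings).
#' @param match,mismatch Nucleotide-mode scores (match must be positive).
#' @param gap_open,gap_extend Non-negative penalties with
#'   `gap_open >= gap_extend`; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return An `hdz_scheme` list: `mode`, `matrix` (alphabet x alphabet),
#'   `alphabet`, `gap_open`, `gap_extend`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 1, mismatch = -2,
                           gap_open = if (mode[1] == "protein") 11 else 5,
                           gap_extend = 1) {
  mode <- match.arg(mode)
  if (gap_open < gap_extend || gap_extend < 0) {
    abort("require gap_open >= gap_extend >= 0")
  }
  if (mode == "nucleotide") {
    if (match <= 0) abort("match score must be > 0 in nucleotide mode")
    mat <- matrix(mismatch, 4, 4,
                  dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
    diag(mat) <- match
  } else {
    full <- get_blosum62()
    mat <- full[AA_ALPHABET, AA_ALPHABET]
  }
  structure(
    list(mode = mode, matrix = mat,
         alphabet = if (mode == "nucleotide") DNA_ALPHABET else AA_ALPHABET,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "hdz_scheme"
  )
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

encode_for_scheme <- function(x, scheme) {
  if (scheme$mode == "nucleotide") encode_dna(x, allow_n = FALSE)
  else encode_aa(x)
}

#' Optimal affine-gap local alignment of two sequences
#'
#' Full Smith-Waterman dynamic programming with affine gap costs. Quadratic
#' time and memory -- intended for sequences up to a few kb; the flank
#' comparison of the duplication stage uses [seeded_local_align()] instead.
#'
#' @param a,b Sequences (single strings) over the scheme's alphabet.
#' @param scheme An [scoring_scheme()].
#' @return One-row tibble (`AlignmentBlock`): `query_id`, `subject_id`,
#'   `qstart`, `qend`, `sstart`, `send` (0-based half-open), `length`
#'   (aligned columns), `matches`, `identity`, `score`. A pair with no
#'   positive-scoring local alignment yields a zero-score empty block.
#' @export
#' @examples
#' smith_waterman("ACGT", "ACGT", scoring_scheme(match = 2))$score # 8
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "hdz_scheme"))
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("both sequences must be nonempty")
  }
  res <- cpp_sw_align(encode_for_scheme(a, scheme),
                      encode_for_scheme(b, scheme),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend)
  tibble(
    query_id = "a", subject_id = "b",
    qstart = res$qstart, qend = res$qend,
    sstart = res$sstart, send = res$send,
    length = res$length, matches = res$matches,
    identity = if (res$length > 0) res$matches / res$length else 0,
    score = res$score
  )
}

#' Seed-and-extend local alignment for long nucleotide sequences
#'
#' Exact k-mer seed matches are greedily extended without gaps under an
#' X-drop rule; blocks on the same diagonal that overlap or lie within
#' `bridge` bases are merged (match counts recomputed over the merged
#' span). Indel-containing homologies surface as several collinear blocks,
#' which the chaining stage assembles. Fully deterministic.
#'
#' @param query,subject Nucleotide sequences over A/C/G/T/N (N never seeds
#'   or matches).
#' @param k Seed length, `>= 8` (default 12).
#' @param scheme Nucleotide [scoring_scheme()]; its match/mismatch scores
#'   drive the extension.
#' @param xdrop Score drop at which extension stops (default 20).
#' @param bridge Same-diagonal merge distance in bases (default 50).
#' @param query_id,subject_id Identifiers copied into the result.
#' @return Tibble of alignment blocks with the [smith_waterman()] columns.
#' @export
seeded_local_align <- function(query, subject, k = 12,
                               scheme = scoring_scheme(),
                               xdrop = 20, bridge = 50,
                               query_id = "query", subject_id = "subject") {
  if (scheme$mode != "nucleotide") {
    abort("seeded_local_align supports nucleotide mode only")
  }
  if (k < 8) abort("seed length k must be >= 8 for nucleotide mode")
  q <- encode_dna(query, allow_n = TRUE)
  s <- encode_dna(subject, allow_n = TRUE)
  match <- scheme$matrix[1, 1]
  mismatch <- scheme$matrix[1, 2]
  m <- cpp_seed_extend(q, s, as.integer(k), match, mismatch, xdrop,
                       as.integer(bridge))
  if (nrow(m) == 0) {
    return(tibble(
      query_id = character(), subject_id = character(),
      qstart = integer(), qend = integer(),
      sstart = integer(), send = integer(),
      length = integer(), matches = integer(),
      identity = double(), score = double()
    ))
  }
  tibble(
    query_id = query_id, subject_id = subject_id,
    qstart = as.integer(m[, "qstart"]), qend = as.integer(m[, "qend"]),
    sstart = as.integer(m[, "sstart"]), send = as.integer(m[, "send"]),
    length = as.integer(m[, "length"]),
    matches = as.integer(m[, "matches"]),
    identity = m[, "matches"] / m[, "length"],
    score = m[, "score"]
  ) |> arrange(desc(.data$score), .data$qstart)
}

#' Write alignment blocks as a tabular hit file
#'
#' Mirrors the common 9-column pairwise-hit layout (identity as percent).
#'
#' @param blocks Tibble of alignment blocks.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  out <- tibble(
    qid = blocks$query_id, sid = blocks$subject_id,
    identity_pct = round(100 * blocks$identity, 2),
    length = blocks$length,
    qstart = blocks$qstart, qend = blocks$qend,
    sstart = blocks$sstart, send = blocks$send,
    score = blocks$score
  )
  readr::write_tsv(out, path)
  invisible(path)
}
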