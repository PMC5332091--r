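# Alphabets, physico-chemical constants and the packaged domain models.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_ALPHABET <- c("A", "C", "G", "T")

# Average residue masses in Da (monoisotopic masses are not used; protein MW
# conventionally reports the average isotopic composition). Water is added
# once per chain.
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Bjellqvist-style pK set for isoelectric-point estimation: side chains plus
# free termini. Sign: acidic groups release a proton (negative charge when
# pH > pK), basic groups bind one (positive when pH < pK).
PK_TABLE <- list(
  nterm = 7.50, cterm = 3.55,
  acidic = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  basic  = c(H = 5.98, K = 10.00, R = 12.00)
)

# IUPAC nucleotide degeneracy codes mapped to the concrete bases they match.
# An N in the scanned sequence never matches any pattern symbol.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Packaged domain consensus sequences. These are synthetic, hand-written
# exemplars with the hallmark features of each domain class (helix-turn-helix
# flavour and the invariant W..N..R core for the homeodomain; leucine heptads
# for the zipper; the eponymous C-P-S-C-E core; long hydrophobic-rich blocks
# for the lipid-binding START region; an acidic C-terminal MEKHLA-like
# block). They are package fixtures that define the synthetic ground truth,
# not database-derived models.
DOMAIN_CONSENSUS <- c(
  HD = paste0("KRRLSADQVQFLEKSFEVENKLEPERKTQLARELGLQPRQVAIWFQNRRAR",
              "WKTKQLEHD"),
  LZ = paste0("YENLKLRFEALKKDNDSLLAQNKKLQAELVELKNKLGAREEVNSSR"),
  CPSCE = "GDCPSCERVGGESA",
  START = paste0("WVEHMDADSWSTVFNEESMSRMFPGAVQSGQCMGVVSGMSERNFVNLAELS",
                 "PDWIKQFPSMIQSAKTIDVLSNGTPGQDAILRMCERMIDGTWVVVDVSVDA",
                 "LRPDSPTHRSFVRGGMQSSGWAILQPVDGGHSTLTYIEHVDLRGWGVPEVL",
                 "RPLYESSILSAGKRIAQALEK"),
  MEKHLA = paste0("MEKHLAGFRDESAWALMSDRETVDEVREALSRGEPFCLMAPHGDFVVLNRS",
                  "PEWVEDFLGEQARAIDIRSASADNGGSSILTVAFQILVNSVPTAKLSLDSV",
                  "STVNDMLAGTIQKIKAAL")
)

# Per-subfamily domain architecture of the HD-Zip family: every member has
# HD + LZ; II adds the CPSCE motif; III and IV add START; MEKHLA marks III
# only. This rule table is a total function over the four archetypes.
SUBFAMILY_ARCHITECTURE <- list(
  I   = c("HD", "LZ"),
  II  = c("HD", "LZ", "CPSCE"),
  III = c("HD", "LZ", "START", "MEKHLA"),
  IV  = c("HD", "LZ", "START")
)

SUBFAMILIES <- c("I", "II", "III", "IV")

#' Packaged domain consensus sequences
#'
#' Returns the synthetic consensus sequences used as seed material for the
#' HD, leucine-zipper, CPSCE, START and MEKHLA domain profiles and by the
#' synthetic-genome generator. These exemplars are authored fixtures of this
#' package (they carry the hallmark residues of each domain class) rather
#' than database-derived models.
#'
#' @return Named character vector with elements `HD`, `LZ`, `CPSCE`,
#'   `START`, `MEKHLA`.
#' @export
#' @examples
#' nchar(domain_consensus()["HD"])
domain_consensus <- function() DOMAIN_CONSENSUS

#' Architecture rule table for HD-Zip subfamilies
#'
#' @return Named list mapping subfamily I--IV to the required domain set.
#' @export
subfamily_architecture <- function() SUBFAMILY_ARCHITECTURE

# integer encodings used by the compiled kernels -------------------------

encode_aa <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], AA_ALPHABET) - 1L
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    abort(sprintf("non-standard residue at position %d of sequence", bad))
  }
  v
}

# A=0 C=1 G=2 T=3, N = -1 (never seeds or matches); any other symbol errors.
encode_dna <- function(x, allow_n = TRUE) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  v <- match(chars, DNA_ALPHABET) - 1L
  isn <- chars == "N"
  if (allow_n) v[isn] <- -1L
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    abort(sprintf("invalid nucleotide '%s' at position %d", chars[bad], bad))
  }
  v
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence at a fixed per-position rate; substitutions are
# uniform over the other letters of the alphabet.
mutate_sequence <- function(x, rate, alphabet = AA_ALPHABET) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(alphabet, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}
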