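# IUPAC codec: DNA strings <-> per-position probability matrices over (A,C,G,T).

# Canonical column order. Any fixed order is equivalent up to permutation of
# the encoding columns; (A,C,G,T) is used throughout and never changed.
.BASES <- c("A", "C", "G", "T")

# IUPAC code -> canonical bases it denotes
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# 15 x 4 row-stochastic encoding table, rows named by IUPAC code
.IUPAC_ENC <- local({
  m <- t(vapply(.IUPAC_SETS, function(b) {
    row <- numeric(4L)
    row[match(b, .BASES)] <- 1 / length(b)
    row
  }, numeric(4L)))
  colnames(m) <- .BASES
  m
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC alphabet used by the package
#'
#' @return Character vector of the 15 IUPAC nucleotide codes.
#' @export
iupac_alphabet <- function() names(.IUPAC_SETS)

# Normalize a sequence string: upper-case, U -> T; error on invalid codes
# with 1-based positions reported.
.normalize_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string")
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% names(.IUPAC_SETS)))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

#' Encode an IUPAC DNA string as a base-probability matrix
#'
#' Each position becomes a probability distribution over the four canonical
#' bases, columns ordered (A, C, G, T): the uniform distribution over the
#' bases compatible with the IUPAC code at that position. `'A'` encodes to
#' `[1,0,0,0]`, `'W'` (A or T) to `[0.5,0,0,0.5]`, `'N'` to four 0.25s.
#' Lowercase is accepted; `U` is treated as `T`.
#'
#' @param seq A single IUPAC DNA string, length >= 1.
#' @return A numeric matrix with `nchar(seq)` rows and 4 columns named
#'   A, C, G, T; every row sums to 1.
#' @examples
#' encode_iupac("AWN")
#' @export
encode_iupac <- function(seq) {
  chars <- .normalize_seq(seq)
  if (!length(chars)) stop("`seq` must have length >= 1")
  m <- .IUPAC_ENC[match(chars, rownames(.IUPAC_ENC)), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Reverse-complement an IUPAC DNA string
#'
#' Applies the standard IUPAC complement table (ambiguity codes map to the
#' complement of their base set: `R`<->`Y`, `W`->`W`, `S`->`S`, `N`->`N`)
#' and reverses the sequence. Involution: applying it twice returns the
#' input.
#'
#' @param seq A single IUPAC DNA string (may be empty).
#' @return The reverse-complemented string, upper-cased.
#' @examples
#' reverse_complement("AAW")  # "WTT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single character string")
  if (!nzchar(seq)) return(seq)
  chars <- .normalize_seq(seq)
  paste(rev(.IUPAC_COMPLEMENT[chars]), collapse = "")
}

# Vectorized reverse complement for many sequences (internal hot path).
# Uses Biostrings for speed on large read sets; semantics identical to
# reverse_complement().
.revcomp_many <- function(seqs) {
  if (!length(seqs)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Pad or truncate an encoded sequence to a fixed width
#'
#' Model inputs have a fixed number of positions (150 by default, the
#' Illumina read length). Shorter inputs are zero-padded at the 3' end
#' (all-zero rows, distinct from `N` which is uniform 0.25); longer inputs
#' keep their first `width` rows. Idempotent at the target width.
#'
#' @param enc A matrix as returned by [encode_iupac()].
#' @param width Target number of rows (positions), default 150.
#' @return A `width` x 4 matrix.
#' @export
shape_to_width <- function(enc, width = 150L) {
  stopifnot(is.matrix(enc), ncol(enc) == 4L, width >= 1L)
  n <- nrow(enc)
  if (n == width) return(enc)
  if (n > width) return(enc[seq_len(width), , drop = FALSE])
  out <- matrix(0, nrow = width, ncol = 4L)
  colnames(out) <- colnames(enc)
  out[seq_len(n), ] <- enc
  out
}

# TRUE for strings containing only IUPAC codes (after case/U normalization)
.valid_iupac <- function(seqs) {
  grepl("^[ACGTUacgtuRYSWKMBDHVNryswkmbdhvn]+$", seqs)
}

# Encode many sequences straight into the flattened model-input layout used
# by the network: one column per sequence, rows indexed base-within-position
# (position-major), length 4*width. Sequences are truncated/zero-padded to
# `width`. Fully vectorized (one match() over all characters); the hot path
# for read classification. Returns a (4*width) x N matrix.
.encode_batch <- function(seqs, width = 150L) {
  n <- length(seqs)
  if (!n) return(matrix(0, nrow = 4L * width, ncol = 0L))
  bad <- which(!.valid_iupac(seqs))
  if (length(bad))
    stop(sprintf("non-IUPAC character in sequence %d", bad[1]))
  s <- chartr("uU", "TT", toupper(substr(seqs, 1L, width)))
  s <- formatC(s, width = -width)            # right-pad with spaces
  chars <- unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE)
  k <- match(chars, rownames(.IUPAC_ENC))    # NA for padding spaces
  k[is.na(k)] <- 16L
  enc_pad <- rbind(.IUPAC_ENC, 0)            # row 16 = zero padding
  v <- enc_pad[k, , drop = FALSE]            # (width*n) x 4, position-major
  out <- aperm(array(v, c(width, n, 4L)), c(3L, 1L, 2L))
  dim(out) <- c(4L * width, n)
  out
}
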