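#' Amino-acid alphabet
#'
#' Twenty canonical residues plus `"X"` for unknown/non-standard residues.
#'
#' @return Character vector of length 21.
#' @export
amino_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y", "X")
}

# run expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# deterministic 31-bit string hash (polynomial, base 31)
string_seed <- function(x, salt = 0L) {
  h <- as.numeric(salt) %% 2147483647
  for (cc in utf8ToInt(x)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Specify a protein embedding backend
#'
#' A backend turns an amino-acid sequence into an L x h per-residue matrix.
#' Available kinds:
#' \describe{
#'   \item{onehot}{One row per residue, one-hot over [amino_alphabet()]
#'     (width 21 by default); unknown letters map to the `"X"` column.}
#'   \item{kmer}{Each residue receives the mean of the vectors of the
#'     k-mers covering it (default k = 3, width 100). The k-mer vector
#'     table is loaded from `table` (named list / matrix rows named by
#'     k-mer) or, when absent, drawn deterministically from a per-k-mer
#'     seeded Gaussian so tests need no external asset.}
#'   \item{tape, esm}{Adapters for pretrained protein language models
#'     (fixed widths 768 and 1280). The models themselves are external;
#'     matrices must be supplied through `cache` (a named list of L x h
#'     matrices keyed by sequence, or a path to an RDS file holding one).
#'     A sequence absent from the cache raises a "backend unavailable"
#'     error - never a silent fallback.}
#'   \item{external}{Like tape/esm but with a caller-chosen `width`.}
#' }
#'
#' @param kind One of `"onehot"`, `"kmer"`, `"tape"`, `"esm"`, `"external"`.
#' @param width Embedding width; fixed per kind except `"external"`.
#' @param k k-mer length (kmer backend).
#' @param alphabet Residue alphabet (onehot backend).
#' @param table Optional k-mer vector table.
#' @param cache Pretrained-embedding cache (named list or RDS path).
#' @param truncate Optional maximum length; longer sequences are tail-
#'   truncated and the truncation is recorded on the result.
#' @param table_seed Integer salt for the deterministic k-mer table.
#' @return An object of class `"embedding_backend"` with a fixed `width`
#'   and a `backend_id` string.
#' @export
embedding_backend <- function(kind = c("onehot", "kmer", "tape", "esm",
                                       "external"),
                              width = NULL, k = 3L,
                              alphabet = amino_alphabet(), table = NULL,
                              cache = NULL, truncate = NULL,
                              table_seed = 1L) {
  kind <- match.arg(kind)
  width <- switch(kind,
    onehot = length(alphabet),
    kmer = if (is.null(width)) 100L else as.integer(width),
    tape = 768L,
    esm = 1280L,
    external = {
      if (is.null(width)) stop("external backend needs an explicit width",
                               call. = FALSE)
      as.integer(width)
    })
  if (!is.null(truncate) && truncate < 1L)
    stop("truncate must be positive", call. = FALSE)
  if (is.character(cache) && length(cache) == 1L) {
    if (!file.exists(cache))
      stop("backend unavailable: embedding cache file not found: ", cache,
           call. = FALSE)
    cache <- readRDS(cache)
  }
  structure(
    list(kind = kind, width = width, k = as.integer(k), alphabet = alphabet,
         table = table, cache = cache, truncate = truncate,
         table_seed = as.integer(table_seed),
         backend_id = sprintf("%s-h%d", kind, width)),
    class = "embedding_backend")
}

kmer_vector <- function(kmer, spec) {
  if (!is.null(spec$table)) {
    v <- if (is.matrix(spec$table)) spec$table[kmer, ] else spec$table[[kmer]]
    if (is.null(v) || anyNA(v))
      stop("k-mer table has no entry for ", kmer, call. = FALSE)
    return(as.numeric(v))
  }
  with_seed(string_seed(kmer, spec$table_seed),
            stats::rnorm(spec$width, sd = 1 / sqrt(spec$width)))
}

#' Embed one amino-acid sequence
#'
#' @param sequence A non-empty amino-acid string.
#' @param spec An [embedding_backend()].
#' @return An object of class `"residue_embedding"`: list with `matrix`
#'   (L x h), `L`, `h`, `backend_id`, `sequence_hash` and `truncated`.
#' @examples
#' e <- embed_sequence("ACDEFG", embedding_backend("onehot"))
#' dim(e$matrix)  # 6 x 21
#' @export
embed_sequence <- function(sequence, spec) {
  stopifnot(inherits(spec, "embedding_backend"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  truncated <- FALSE
  if (!is.null(spec$truncate) && nchar(sequence) > spec$truncate) {
    sequence <- substr(sequence, 1L, spec$truncate)
    truncated <- TRUE
  }
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)

  m <- switch(spec$kind,
    onehot = {
      idx <- match(chars, spec$alphabet)
      idx[is.na(idx)] <- match("X", spec$alphabet) %||% length(spec$alphabet)
      out <- matrix(0, L, spec$width)
      out[cbind(seq_len(L), idx)] <- 1
      out
    },
    kmer = {
      k <- spec$k
      padded <- if (L < k) paste0(sequence,
                                  strrep("X", k - L)) else sequence
      n_k <- max(nchar(padded) - k + 1L, 1L)
      kv <- t(vapply(seq_len(n_k),
                     function(s) kmer_vector(substr(padded, s, s + k - 1L),
                                             spec),
                     numeric(spec$width)))
      out <- matrix(0, L, spec$width)
      for (i in seq_len(L)) {
        cover <- seq(max(1L, i - k + 1L), min(i, n_k))
        out[i, ] <- colMeans(kv[cover, , drop = FALSE])
      }
      out
    },
    { # tape / esm / external: cache lookup only
      entry <- spec$cache[[sequence]]
      if (is.null(entry))
        stop("backend unavailable: no cached '", spec$kind,
             "' embedding for this sequence; supply `cache` with ",
             "precomputed matrices (model assets are external)",
             call. = FALSE)
      entry <- as.matrix(entry)
      if (nrow(entry) != L || ncol(entry) != spec$width)
        stop("cached embedding has shape ", nrow(entry), "x", ncol(entry),
             ", expected ", L, "x", spec$width, call. = FALSE)
      entry
    })

  if (!all(is.finite(m))) stop("non-finite embedding values", call. = FALSE)
  structure(
    list(matrix = m, L = L, h = spec$width, backend_id = spec$backend_id,
         sequence_hash = sequence_digest(sequence), truncated = truncated),
    class = "residue_embedding")
}

#' Digest of an amino-acid sequence
#'
#' @param sequence A string.
#' @return MD5 digest (character).
#' @export
sequence_digest <- function(sequence) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(sequence, f, eos = NULL)
  unname(tools::md5sum(f))
}

#' Embed a corpus of sequences with disk caching
#'
#' One cache entry per distinct sequence, keyed by `(digest, backend_id)`.
#' Re-running on a complete cache performs no new computation; a partial
#' cache is resumed.
#'
#' @param sequences Character vector of sequences (duplicates collapsed).
#' @param spec An [embedding_backend()].
#' @param cache_path RDS file the cache lives in (created if absent).
#' @return Invisibly, list with `cache_path`, `n_total`, `n_new`,
#'   `n_reused`.
#' @export
embed_corpus <- function(sequences, spec, cache_path) {
  stopifnot(inherits(spec, "embedding_backend"))
  sequences <- unique(toupper(sequences))
  if (!length(sequences)) stop("no sequences to embed", call. = FALSE)
  dir <- dirname(cache_path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("cache path not writable: ", cache_path, call. = FALSE)
  cache <- if (file.exists(cache_path)) readRDS(cache_path) else list()
  n_new <- 0L
  for (s in sequences) {
    key <- paste0(sequence_digest(s), ":", spec$backend_id)
    hit <- cache[[key]]
    if (!is.null(hit) && identical(hit$backend_id, spec$backend_id) &&
        identical(ncol(hit$matrix), as.integer(spec$width))) next
    e <- embed_sequence(s, spec)
    cache[[key]] <- list(matrix = e$matrix, backend_id = e$backend_id,
                         h = e$h, sequence_hash = e$sequence_hash)
    n_new <- n_new + 1L
  }
  if (n_new > 0L) saveRDS(cache, cache_path)
  invisible(list(cache_path = cache_path, n_total = length(sequences),
                 n_new = n_new, n_reused = length(sequences) - n_new))
}

#' Fetch a cached embedding
#'
#' @param sequence Sequence string.
#' @param spec The backend it was cached under.
#' @param cache_path Cache file written by [embed_corpus()].
#' @return A `residue_embedding`.
#' @export
cached_embedding <- function(sequence, spec, cache_path) {
  cache <- readRDS(cache_path)
  sequence <- toupper(sequence)
  key <- paste0(sequence_digest(sequence), ":", spec$backend_id)
  hit <- cache[[key]]
  if (is.null(hit)) stop("sequence not in cache", call. = FALSE)
  structure(list(matrix = hit$matrix, L = nrow(hit$matrix), h = hit$h,
                 backend_id = hit$backend_id,
                 sequence_hash = hit$sequence_hash, truncated = FALSE),
            class = "residue_embedding")
}

#' @export
print.residue_embedding <- function(x, ...) {
  cat(sprintf("<residue_embedding> L=%d h=%d backend=%s\n", x$L, x$h,
              x$backend_id))
  invisible(x)
}
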