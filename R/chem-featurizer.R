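#' Atom element vocabulary
#'
#' The frozen, ordered 44-symbol element vocabulary used by the default
#' atom-feature scheme. The final slot, `"other"`, absorbs any element
#' outside the list so that feature vectors keep a fixed width.
#'
#' @return Character vector of length 44.
#' @export
cpi_elements <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca",
    "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag",
    "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni",
    "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg", "Pb", "other")
}

#' Atom feature scheme
#'
#' Describes the per-atom binary feature layout: a 44-wide element one-hot,
#' an 11-wide heavy-atom degree one-hot (degrees 0-10, larger clamped to the
#' last slot), an 11-wide total-hydrogen one-hot, an 11-wide
#' implicit-hydrogen one-hot, and a single aromaticity flag - 78 bits in
#' total.
#'
#' `degree_counts_h = TRUE` switches the degree block to count bonded
#' hydrogens as neighbours as well (total coordination number); the default
#' counts heavy-atom neighbours only.
#'
#' @param elements Ordered element vocabulary; last entry is the
#'   catch-all slot.
#' @param onehot_width Width of each of the three count one-hot blocks.
#' @param degree_counts_h Logical; include bonded H atoms in the degree.
#' @return An object of class `"cpi_feature_scheme"`.
#' @export
feature_scheme <- function(elements = cpi_elements(), onehot_width = 11L,
                           degree_counts_h = FALSE) {
  stopifnot(length(elements) >= 2L, onehot_width >= 1L)
  structure(
    list(elements = elements, onehot_width = as.integer(onehot_width),
         degree_counts_h = isTRUE(degree_counts_h),
         width = length(elements) + 3L * as.integer(onehot_width) + 1L),
    class = "cpi_feature_scheme")
}

# openbabel conversion via ChemmineOB; addh=TRUE makes every hydrogen explicit
ob_mol2 <- function(smiles, addh = FALSE) {
  opts <- if (addh) data.frame(names = "h", args = "", stringsAsFactors = FALSE)
          else data.frame(names = character(0), args = character(0))
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", source = smiles,
                                               options = opts)),
    error = function(e) "")
  if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt, fixed = TRUE))
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  txt
}

# Minimal TRIPOS MOL2 reader: returns atoms (element, sybyl type) and bonds
# (i, j, type). Fixed whitespace-separated format as emitted by openbabel.
parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sec <- function(tag) {
    i <- which(lines == tag)
    if (!length(i)) return(character(0))
    i <- i[1] + 1L
    j <- i
    while (j <= length(lines) && !startsWith(lines[j], "@<TRIPOS>")) j <- j + 1L
    out <- lines[seq(i, length.out = max(0L, j - i))]
    out[nzchar(trimws(out))]
  }
  at <- sec("@<TRIPOS>ATOM")
  if (!length(at)) stop("MOL2 block without atoms", call. = FALSE)
  af <- strsplit(trimws(at), "\\s+")
  sybyl <- vapply(af, `[[`, "", 6L)
  atoms <- data.frame(element = sub("\\..*$", "", sybyl), sybyl = sybyl,
                      stringsAsFactors = FALSE)
  bd <- sec("@<TRIPOS>BOND")
  if (length(bd)) {
    bf <- strsplit(trimws(bd), "\\s+")
    bonds <- data.frame(i = as.integer(vapply(bf, `[[`, "", 2L)),
                        j = as.integer(vapply(bf, `[[`, "", 3L)),
                        type = vapply(bf, `[[`, "", 4L),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), type = character(0),
                        stringsAsFactors = FALSE)
  }
  list(atoms = atoms, bonds = bonds)
}

count_neighbours <- function(n_atoms, bonds, keep) {
  # keep: logical over atoms; counts, per atom, bonded neighbours with keep=TRUE
  cnt <- integer(n_atoms)
  if (nrow(bonds)) {
    ik <- keep[bonds$j]   # neighbour of i is j
    jk <- keep[bonds$i]
    cnt <- tabulate(c(bonds$i[ik], bonds$j[jk]), nbins = n_atoms)
  }
  cnt
}

onehot_clamped <- function(value, width) {
  slot <- pmin(value, width - 1L) + 1L
  m <- matrix(0, length(value), width)
  m[cbind(seq_along(value), slot)] <- 1
  m
}

#' Convert a SMILES string into an attributed molecular graph
#'
#' Builds the heavy-atom graph of a compound: one node per non-hydrogen
#' atom, an undirected edge per chemical bond, and per-node binary feature
#' vectors laid out per [feature_scheme()] (element, degree, total H,
#' implicit H, aromaticity). Hydrogens enter as node features, never as
#' nodes. Chemistry (valence, aromaticity perception, hydrogen saturation)
#' is delegated to openbabel through ChemmineOB.
#'
#' @param smiles A single SMILES string.
#' @param scheme A [feature_scheme()].
#' @return An object of class `"molecular_graph"`: list with
#'   `node_features` (N x 78 binary matrix), `edges` (two-column integer
#'   matrix of atom-index pairs, i < j), `smiles` (input string),
#'   `canonical` (canonical SMILES), `atom_count`, `elements` (character
#'   per node) and `feature_width`.
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$atom_count     # 6
#' nrow(g$edges)    # 6
#' @export
smiles_to_graph <- function(smiles, scheme = feature_scheme()) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("smiles must be a single non-empty string", call. = FALSE)
  stopifnot(inherits(scheme, "cpi_feature_scheme"))

  plain <- parse_mol2(ob_mol2(smiles, addh = FALSE))
  full <- parse_mol2(ob_mol2(smiles, addh = TRUE))

  heavy_f <- full$atoms$element != "H"
  heavy_p <- plain$atoms$element != "H"
  if (!any(heavy_f))
    stop("unparseable SMILES (no heavy atoms): ", smiles, call. = FALSE)
  if (!identical(full$atoms$element[heavy_f], plain$atoms$element[heavy_p]))
    stop("internal: atom order mismatch between conversions for ", smiles,
         call. = FALSE)

  n_full <- nrow(full$atoms)
  deg_heavy <- count_neighbours(n_full, full$bonds, heavy_f)[heavy_f]
  total_h <- count_neighbours(n_full, full$bonds, !heavy_f)[heavy_f]
  expl_h <- count_neighbours(nrow(plain$atoms), plain$bonds,
                             !heavy_p)[heavy_p]
  impl_h <- pmax(total_h - expl_h, 0L)

  arom <- rep(FALSE, n_full)
  ar_b <- full$bonds$type == "ar"
  arom[c(full$bonds$i[ar_b], full$bonds$j[ar_b])] <- TRUE
  arom <- arom | grepl("\\.ar$", full$atoms$sybyl)
  arom <- arom[heavy_f]

  elem <- full$atoms$element[heavy_f]
  n <- length(elem)
  slot <- match(elem, scheme$elements)
  slot[is.na(slot)] <- length(scheme$elements)  # reserved "other" slot
  elem_block <- matrix(0, n, length(scheme$elements))
  elem_block[cbind(seq_len(n), slot)] <- 1

  degree <- if (scheme$degree_counts_h) deg_heavy + total_h else deg_heavy
  w <- scheme$onehot_width
  node_features <- cbind(elem_block,
                         onehot_clamped(degree, w),
                         onehot_clamped(total_h, w),
                         onehot_clamped(impl_h, w),
                         as.numeric(arom))

  # relabel heavy-heavy bonds to heavy indices, i < j, no self loops
  idx <- cumsum(heavy_f)
  hb <- full$bonds[heavy_f[full$bonds$i] & heavy_f[full$bonds$j], , drop = FALSE]
  edges <- cbind(idx[hb$i], idx[hb$j])
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges[edges[, 1L] != edges[, 2L], , drop = FALSE])
  } else {
    edges <- matrix(integer(0), 0L, 2L)
  }
  storage.mode(edges) <- "integer"

  structure(
    list(node_features = node_features, edges = edges, smiles = smiles,
         canonical = canonical_smiles(smiles), atom_count = n,
         elements = elem, feature_width = scheme$width),
    class = "molecular_graph")
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) "")
    out <- trimws(sub("\t.*$", "", strsplit(out, "\n")[[1]][1]))
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Featurize every distinct compound of a pair table
#'
#' Deduplicates compounds by canonical SMILES and featurizes each once.
#' Unparseable SMILES are collected into a failure report instead of
#' aborting, unless every compound fails.
#'
#' @param records A data frame with a `compound_smiles` column (e.g. a
#'   [read_pair_table()] result), or a character vector of SMILES.
#' @param scheme A [feature_scheme()].
#' @return List with `graphs` (named by canonical SMILES), `key_map`
#'   (named character: input SMILES -> canonical key) and `failures`
#'   (character vector of offending SMILES).
#' @export
graphs_from_table <- function(records, scheme = feature_scheme()) {
  smiles <- if (is.data.frame(records)) records$compound_smiles else records
  if (is.null(smiles) || !length(smiles))
    stop("no compounds to featurize", call. = FALSE)
  smiles <- unique(as.character(smiles))
  canon <- canonical_smiles(smiles)
  failures <- smiles[is.na(canon)]
  key_map <- structure(canon, names = smiles)
  graphs <- list()
  for (i in seq_along(smiles)) {
    key <- canon[i]
    if (is.na(key) || !is.null(graphs[[key]])) next
    g <- tryCatch(smiles_to_graph(smiles[i], scheme), error = function(e) NULL)
    if (is.null(g)) failures <- c(failures, smiles[i]) else graphs[[key]] <- g
  }
  if (!length(graphs))
    stop("all SMILES failed to featurize (", length(failures), " failures)",
         call. = FALSE)
  list(graphs = graphs, key_map = key_map[!is.na(key_map)],
       failures = unique(failures))
}

#' Read compounds from an SDF file as SMILES
#'
#' @param path Path to an SDF file.
#' @return Character vector of canonical SMILES, one per molecule record.
#' @export
sdf_to_smiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- tempfile(fileext = ".smi")
  on.exit(unlink(out))
  ChemmineOB::convertFormatFile("SDF", "CAN", fromFile = path, toFile = out)
  smi <- readLines(out)
  smi <- trimws(sub("[\t ].*$", "", smi))
  smi[nzchar(smi)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an on-disk molecular graph cache
#'
#' The cache is keyed by canonical SMILES; re-writing merges with any
#' existing cache at `path`.
#'
#' @param graphs Named list of `molecular_graph` objects (canonical keys).
#' @param path Cache file path.
#' @return `write_graph_cache()` the path, invisibly; `read_graph_cache()`
#'   the named list.
#' @export
write_graph_cache <- function(graphs, path) {
  old <- if (file.exists(path)) readRDS(path) else list()
  old[names(graphs)] <- graphs
  saveRDS(old, path)
  invisible(path)
}

#' @rdname write_graph_cache
#' @export
read_graph_cache <- function(path) {
  if (!file.exists(path)) stop("no such graph cache: ", path, call. = FALSE)
  readRDS(path)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s\n  atoms: %d  edges: %d  feature width: %d\n",
              x$smiles, x$atom_count, nrow(x$edges), x$feature_width))
  invisible(x)
}
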