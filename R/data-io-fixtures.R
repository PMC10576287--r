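#' Read a compound-protein pair table
#'
#' Reads a comma- or tab-delimited table of (compound, protein, label)
#' observations. Required columns (after applying `column_map`):
#' `compound_smiles`, one of `protein_sequence` / `protein_id`, and
#' `label`. `protein_id` columns are resolved to sequences against a
#' FASTA file.
#'
#' Malformed rows (unparseable label for the declared task) are collected
#' into an error report attached as `attr(x, "errors")` (with line
#' numbers) and dropped; with `strict = TRUE` any malformed row aborts.
#'
#' @param path File path.
#' @param task `"regression"` (numeric labels) or `"classification"`
#'   (0/1, or the strings activating/inhibiting, active/inactive).
#' @param column_map Optional named character vector mapping required
#'   names to the file's column names, e.g.
#'   `c(compound_smiles = "smiles", label = "pic50")`.
#' @param fasta Optional FASTA path used to resolve `protein_id`.
#' @param delim Field delimiter; auto-detected among comma/tab if `NULL`.
#' @param strict Abort on any malformed row.
#' @return A data frame of class `"pair_table"` with columns
#'   `compound_smiles`, `protein_sequence`, optionally `protein_id`, and
#'   `label`; malformed-row report in `attr(, "errors")`.
#' @export
read_pair_table <- function(path, task = c("regression", "classification"),
                            column_map = NULL, fasta = NULL, delim = NULL,
                            strict = FALSE) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop("column_map names missing column '", src, "'", call. = FALSE)
      names(df)[names(df) == src] <- std
    }
  }
  if (!"compound_smiles" %in% names(df))
    stop("missing required column: compound_smiles", call. = FALSE)
  if (!any(c("protein_sequence", "protein_id") %in% names(df)))
    stop("missing required column: protein_sequence or protein_id",
         call. = FALSE)
  if (!"label" %in% names(df))
    stop("missing required column: label", call. = FALSE)
  if (!nrow(df)) stop("empty pair table: ", path, call. = FALSE)

  if (!"protein_sequence" %in% names(df)) {
    if (is.null(fasta))
      stop("protein_id column requires a fasta= argument", call. = FALSE)
    seqs <- read_fasta(fasta)
    missing <- setdiff(unique(df$protein_id), names(seqs))
    if (length(missing))
      stop("protein_id not found in FASTA: ",
           paste(missing, collapse = ", "), call. = FALSE)
    df$protein_sequence <- unname(seqs[df$protein_id])
  }

  raw <- df$label
  if (task == "regression") {
    lab <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(lab) | !is.finite(lab))
  } else {
    lab <- map_binary_label(raw)
    bad <- which(is.na(lab))
  }
  errors <- NULL
  if (length(bad)) {
    errors <- data.frame(line = bad + 1L, label = as.character(raw[bad]))
    if (strict)
      stop("malformed label(s) at line(s) ",
           paste(errors$line, collapse = ", "), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    lab <- lab[-bad]
  }
  if (!nrow(df)) stop("no well-formed rows in ", path, call. = FALSE)
  df$label <- lab
  structure(df, class = c("pair_table", "data.frame"), task = task,
            errors = errors, source = path)
}

map_binary_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "active", "activating", "positive", "true")] <- 1L
  out[x %in% c("0", "inactive", "inhibiting", "negative", "false")] <- 0L
  out
}

#' Write a pair table
#'
#' @param x A data frame (e.g. a `pair_table`).
#' @param path Output path; extension `.tsv` selects tab, else comma.
#' @return The path, invisibly.
#' @export
write_pair_table <- function(x, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Uses Biostrings when available; otherwise a plain-text reader.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (names = record IDs up to
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readAAStringSet(path)
    out <- as.character(s)
    names(out) <- sub("\\s.*$", "", names(s))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  structure(toupper(seqs), names = id)
}

#' Specification for the synthetic CPI benchmark generator
#'
#' The generator emulates the structure of public CPI benchmarks: a
#' many-to-many compound x protein grid with continuous pIC50 labels from
#' a planted linear model, and classification labels derived by the
#' standard affinity thresholds (positive below 100 nM, i.e. pIC50 > 7;
#' negative above 10 uM, i.e. pIC50 < 5; the intermediate zone dropped).
#'
#' Compounds are assembled from a fixed fragment vocabulary on ring
#' scaffolds so every SMILES parses; the latent potency of a compound is
#' the sum of its planted fragment effects, each target scales it by a
#' planted sensitivity and offsets it by a baseline, and Gaussian noise of
#' sd `noise_sd` is added. The latent scale puts pIC50 roughly in [3, 10].
#'
#' Proteins are organized into sequence families (a base sequence plus
#' members diverged at a fraction `family_divergence` of positions, each
#' member with its own sensitivity and baseline), mirroring the family
#' structure of real target panels; distinguishing close homologs is part
#' of what the benchmark tests.
#'
#' @param n_proteins,n_compounds Grid dimensions.
#' @param n_families Number of protein families the proteins are drawn
#'   from (default: about three members per family).
#' @param family_divergence Fraction of positions mutated between family
#'   members (default 0.1, echoing the ~90 percent identity of real
#'   paralog pairs).
#' @param density Fraction of grid cells emitted as pairs (in (0, 1]).
#' @param noise_sd Label noise standard deviation (pIC50 units).
#' @param task `"regression"` or `"classification"`.
#' @param pos_threshold,neg_threshold pIC50 thresholds for the positive /
#'   negative classes (must satisfy neg < pos).
#' @param protein_length Length range of the random protein sequences.
#' @param selectivity Optional list for a two-target selectivity panel:
#'   `selective_fraction` (share of compounds planted selective) and
#'   `delta` (planted pIC50 difference, must exceed `noise_sd`).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_proteins = 10L, n_compounds = 50L,
                           n_families = max(1L, round(n_proteins / 3)),
                           family_divergence = 0.1,
                           density = 1.0, noise_sd = 0.3,
                           task = c("regression", "classification"),
                           pos_threshold = 7, neg_threshold = 5,
                           protein_length = c(40L, 60L),
                           selectivity = NULL, seed = 1L) {
  task <- match.arg(task)
  if (family_divergence <= 0 || family_divergence > 1)
    stop("family_divergence must be in (0, 1]", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]",
                                        call. = FALSE)
  if (neg_threshold >= pos_threshold)
    stop("thresholds must satisfy neg < pos", call. = FALSE)
  if (!is.null(selectivity)) {
    selectivity$selective_fraction <- selectivity$selective_fraction %||% 0.2
    selectivity$delta <- selectivity$delta %||% 2.0
    if (selectivity$delta <= noise_sd)
      stop("planted delta must exceed the noise sd", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_compounds = as.integer(n_compounds),
                 n_families = as.integer(n_families),
                 family_divergence = family_divergence, density = density,
                 noise_sd = noise_sd, task = task,
                 pos_threshold = pos_threshold,
                 neg_threshold = neg_threshold,
                 protein_length = as.integer(protein_length),
                 selectivity = selectivity, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# fragment vocabulary: substituents with planted effect slots
cpi_fragments <- function() {
  c("F", "Cl", "Br", "I", "C", "CC", "CCC", "O", "OC", "N", "NC",
    "C(=O)O", "C(=O)N", "C(F)(F)F", "C#N", "S", "SC", "CO", "CN", "CCO")
}

cpi_scaffolds <- function() {
  c(benzene = "c1ccc(%s)cc1", pyridine = "c1ccnc(%s)c1",
    cyclohexane = "C1CCC(%s)CC1", furan = "c1cc(%s)co1",
    thiophene = "c1cc(%s)cs1")
}

# Random protein with a per-protein Dirichlet-drawn residue composition:
# real proteins differ in amino-acid composition, and compositionally
# distinct sequences are what make targets distinguishable to a
# sequence encoder.
random_protein <- function(len, alpha = 3) {
  w <- stats::rgamma(20L, alpha)
  paste(sample(amino_alphabet()[1:20], len, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

#' Generate a synthetic CPI benchmark
#'
#' See [synthetic_spec()] for the label model. The ground truth (fragment
#' effects, per-target sensitivities and baselines, latent noiseless
#' scores, planted selective set) is returned in a separate `truth`
#' element - and written to a separate sidecar file by
#' [write_synthetic()] - so a model under test never sees it.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `pairs` (a `pair_table`: compound_smiles, protein_id,
#'   protein_sequence, label), `proteins` (named sequences), `truth`, and
#'   `spec`. With a `selectivity` option the pair table covers exactly two
#'   targets (`T_A`, `T_B`) and `truth$selective` names the planted
#'   selective compounds.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    frags <- cpi_fragments()
    effects <- stats::rnorm(length(frags), 0, 0.8)
    names(effects) <- frags
    scaff <- cpi_scaffolds()
    scaff_eff <- stats::rnorm(length(scaff), 0, 0.4)
    names(scaff_eff) <- names(scaff)

    smiles <- character(0)
    canon_seen <- character(0)
    potency <- numeric(0)
    frag_sets <- list()
    tries <- 0L
    while (length(smiles) < spec$n_compounds && tries < 50L * spec$n_compounds) {
      tries <- tries + 1L
      sc <- sample(names(scaff), 1L)
      # a second substituent is grafted onto the ring-closure carbon, which
      # only ring systems closing on C tolerate
      k <- if (sc %in% c("benzene", "pyridine", "cyclohexane"))
        sample(1:2, 1L) else 1L
      fs <- sample(frags, k, replace = TRUE)
      smi <- if (k == 2L) paste0(sprintf(scaff[[sc]], fs[1L]), fs[2L]) else
        sprintf(scaff[[sc]], fs[1L])
      can <- canonical_smiles(smi)
      # distinct molecules, not just distinct spellings
      if (is.na(can) || can %in% canon_seen) next
      smiles <- c(smiles, smi)
      canon_seen <- c(canon_seen, can)
      potency <- c(potency, scaff_eff[[sc]] + sum(effects[fs]))
      frag_sets[[length(smiles)]] <- fs
    }
    if (length(smiles) < spec$n_compounds)
      stop("could not assemble enough distinct compounds", call. = FALSE)
    compound_ids <- sprintf("CPD%03d", seq_along(smiles))

    two_target <- !is.null(spec$selectivity)
    n_prot <- if (two_target) 2L else spec$n_proteins
    mutate_seq <- function(s, frac) {
      ch <- strsplit(s, "")[[1L]]
      mut <- sample(length(ch), max(1L, round(frac * length(ch))))
      ch[mut] <- sample(amino_alphabet()[1:20], length(mut), replace = TRUE)
      paste(ch, collapse = "")
    }
    proteins <- character(n_prot)
    if (two_target) {
      # two close homologs diverged at family_divergence of positions
      base_seq <- random_protein(sample(spec$protein_length[1L]:
                                          spec$protein_length[2L], 1L))
      proteins[1L] <- base_seq
      proteins[2L] <- mutate_seq(base_seq, spec$family_divergence)
      names(proteins) <- c("T_A", "T_B")
    } else {
      # families: a base sequence per family, members are diverged copies
      fam <- rep(seq_len(spec$n_families), length.out = n_prot)
      bases <- vapply(seq_len(spec$n_families), function(i)
        random_protein(sample(spec$protein_length[1L]:
                                spec$protein_length[2L], 1L)), "")
      for (i in seq_len(n_prot))
        proteins[i] <- mutate_seq(bases[fam[i]], spec$family_divergence)
      names(proteins) <- sprintf("T%02d", seq_len(n_prot))
    }
    sens <- stats::runif(n_prot, 0.6, 1.4)
    base <- stats::runif(n_prot, 5.0, 7.5)
    names(sens) <- names(base) <- names(proteins)

    sel_set <- character(0)
    marker <- NA_character_
    sel_delta <- numeric(length(smiles))
    if (two_target) {
      sens[2L] <- sens[1L]   # homologs share sensitivity...
      base[2L] <- base[1L]   # ...and baseline; selectivity is planted
      # selectivity is carried by a structural marker: the fragment whose
      # carrier share is closest to the requested selective fraction, so
      # that selectivity is learnable from compound structure
      carriers <- vapply(frags, function(f)
        sum(vapply(frag_sets, function(fs) f %in% fs, logical(1))),
        numeric(1))
      target_n <- max(1L, round(spec$selectivity$selective_fraction *
                                  length(smiles)))
      ok <- carriers >= 1L
      marker <- frags[ok][which.min(abs(carriers[ok] - target_n))]
      sel_idx <- which(vapply(frag_sets, function(fs) marker %in% fs,
                              logical(1)))
      sel_set <- compound_ids[sel_idx]
      sel_delta[sel_idx] <- spec$selectivity$delta
    }

    grid <- expand.grid(ci = seq_along(smiles), pi = seq_len(n_prot))
    keep <- sort(sample(nrow(grid), round(spec$density * nrow(grid))))
    grid <- grid[keep, , drop = FALSE]
    latent <- base[grid$pi] + sens[grid$pi] * potency[grid$ci] +
      ifelse(grid$pi == 1L, sel_delta[grid$ci] / 2,
             ifelse(grid$pi == 2L, -sel_delta[grid$ci] / 2, 0))
    label <- latent + stats::rnorm(nrow(grid), 0, spec$noise_sd)

    pairs <- data.frame(compound_id = compound_ids[grid$ci],
                        compound_smiles = smiles[grid$ci],
                        protein_id = names(proteins)[grid$pi],
                        protein_sequence = unname(proteins[grid$pi]),
                        label = label, stringsAsFactors = FALSE)
    if (spec$task == "classification") {
      keep2 <- latent > spec$pos_threshold | latent < spec$neg_threshold
      pairs <- pairs[keep2, , drop = FALSE]
      latent_kept <- latent[keep2]
      pairs$label <- as.integer(latent_kept > spec$pos_threshold)
      latent <- latent_kept
    }
    rownames(pairs) <- NULL
    class(pairs) <- c("pair_table", "data.frame")
    attr(pairs, "task") <- spec$task

    list(pairs = pairs, proteins = proteins,
         truth = list(fragment_effects = effects,
                      scaffold_effects = scaff_eff,
                      potency = structure(potency, names = compound_ids),
                      sensitivity = sens, baseline = base,
                      selective = sel_set, marker_fragment = marker,
                      selective_delta = structure(sel_delta,
                                                  names = compound_ids),
                      latent = latent),
         spec = spec)
  })
}

#' Write a synthetic benchmark to disk
#'
#' Emits the pair table (TSV), the protein FASTA, and the ground-truth
#' sidecar (JSON) as separate files.
#'
#' @param syn A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pairs = file.path(dir, "pairs.tsv"),
             fasta = file.path(dir, "proteins.fasta"),
             truth = file.path(dir, "truth.json"))
  write_pair_table(syn$pairs, paths[["pairs"]])
  writeLines(paste0(">", names(syn$proteins), "\n", syn$proteins),
             paths[["fasta"]])
  jsonlite::write_json(syn$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Bundle pairs, graphs and embeddings into a model-ready dataset
#'
#' @param pairs Data frame with `compound_key`, `protein_key`, `label`.
#' @param graphs Named list of `molecular_graph`, keyed by compound key.
#' @param embeddings Named list of `residue_embedding`, keyed by protein
#'   key.
#' @return A `"cpi_dataset"`.
#' @export
cpi_dataset <- function(pairs, graphs, embeddings) {
  stopifnot(is.data.frame(pairs),
            all(c("compound_key", "protein_key", "label") %in% names(pairs)))
  miss_g <- setdiff(unique(pairs$compound_key), names(graphs))
  if (length(miss_g)) stop("graphs missing for: ",
                           paste(utils::head(miss_g, 3L), collapse = ", "),
                           call. = FALSE)
  miss_e <- setdiff(unique(pairs$protein_key), names(embeddings))
  if (length(miss_e)) stop("embeddings missing for: ",
                           paste(utils::head(miss_e, 3L), collapse = ", "),
                           call. = FALSE)
  structure(list(pairs = pairs, graphs = graphs, embeddings = embeddings),
            class = "cpi_dataset")
}

check_dataset <- function(data, task) {
  stopifnot(inherits(data, "cpi_dataset"))
  y <- data$pairs$label
  if (task == "regression") {
    if (!is.numeric(y) || !all(is.finite(y)))
      stop("regression labels must be finite numerics", call. = FALSE)
  } else if (!all(y %in% c(0, 1))) {
    stop("classification labels must be 0/1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Subset a dataset by pair-row indices
#'
#' @param data A [cpi_dataset()].
#' @param idx Row indices of `data$pairs`.
#' @return A `"cpi_dataset"` over the selected pairs (graph and embedding
#'   stores are shared, not copied).
#' @export
subset_dataset <- function(data, idx) {
  out <- data
  out$pairs <- data$pairs[idx, , drop = FALSE]
  rownames(out$pairs) <- NULL
  out
}

#' Build a model-ready dataset from a pair table
#'
#' Featurizes every distinct compound, embeds every distinct protein, and
#' keys pairs by canonical SMILES and sequence digest (or `protein_id`
#' when present).
#'
#' @param table A `pair_table` (e.g. [read_pair_table()] or
#'   [generate_synthetic()]`$pairs`).
#' @param backend An [embedding_backend()].
#' @param scheme A [feature_scheme()].
#' @return A `"cpi_dataset"`.
#' @export
build_dataset <- function(table, backend = embedding_backend("onehot"),
                          scheme = feature_scheme()) {
  ft <- graphs_from_table(table, scheme)
  if (length(ft$failures))
    warning(length(ft$failures), " compound(s) failed to featurize")
  ckey <- unname(ft$key_map[table$compound_smiles])
  pkey <- if ("protein_id" %in% names(table)) table$protein_id else
    vapply(table$protein_sequence, sequence_digest, "", USE.NAMES = FALSE)
  seqs <- table$protein_sequence
  embeddings <- list()
  for (i in which(!duplicated(pkey)))
    embeddings[[pkey[i]]] <- embed_sequence(seqs[i], backend)
  ok <- !is.na(ckey)
  pairs <- data.frame(compound_key = ckey[ok], protein_key = pkey[ok],
                      label = table$label[ok], stringsAsFactors = FALSE)
  cpi_dataset(pairs, ft$graphs, embeddings)
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version and input digests of
#' a run next to its outputs.
#'
#' @param dir Output directory.
#' @param config Named list of run parameters.
#' @param inputs Character vector of input file paths (digested).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "cpifuse",
         version = as.character(utils::packageVersion("cpifuse")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, input_digests = digests),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
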