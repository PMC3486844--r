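#' Load a conformational ensemble of Calpha atoms
#'
#' Reads a multi-model PDB file or a DCD trajectory (with a PDB topology) and
#' returns the ordered Calpha conformers. Alternate locations are resolved to
#' the highest-occupancy atom (alphabetic altloc id as tie-break); insertion
#' codes are rejected rather than silently reordered.
#'
#' @param path file path.
#' @param format `"pdb_multimodel"` or `"trajectory"` (DCD; XTC/TRR have no
#'   installed reader and raise an error naming the format).
#' @param topology PDB file defining atoms/residues; required for trajectories.
#' @param dt frame spacing in ps (optional; populates frame times).
#' @return a `calpha_ensemble`.
#' @export
load_ensemble <- function(path, format = c("pdb_multimodel", "trajectory"),
                          topology = NULL, dt = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb_multimodel") {
    check_model_ca_counts(path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
    if (is.null(dim(pdb$xyz))) pdb$xyz <- matrix(pdb$xyz, nrow = 1L)
    ca <- calpha_rows(pdb)
    labels <- ca$labels
    xyz <- pdb$xyz[, ca$xyz_cols, drop = FALSE]
    if (nrow(xyz) < 1L) stop("zero frames in ", path)
    calpha_ensemble(xyz, labels = labels, dt = dt)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("xtc", "trr"))
      stop("no reader available for ", toupper(ext),
           " trajectories; convert to DCD or multi-model PDB")
    if (is.null(topology)) stop("trajectory format requires a PDB topology")
    pdb <- bio3d::read.pdb(topology, verbose = FALSE)
    traj <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(traj) != 3L * nrow(pdb$atom))
      stop("trajectory atom count does not match topology")
    ca <- calpha_rows(pdb)
    calpha_ensemble(traj[, ca$xyz_cols, drop = FALSE], labels = ca$labels, dt = dt)
  }
}

# Validate that every MODEL block of a PDB file carries the same number of
# Calpha ATOM records (cheap pre-check; the actual parse is bio3d's).
check_model_ca_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records in ", path)
  counts <- mapply(function(s, e) {
    blk <- lines[s:e]
    sum(grepl("^ATOM", blk) & substr(blk, 13L, 16L) == " CA ")
  }, starts, ends)
  if (length(unique(counts)) != 1L)
    stop("inconsistent Calpha count across models: ", paste(counts, collapse = ", "))
  invisible(TRUE)
}

# Pick the Calpha atom rows of a bio3d pdb object (altloc resolution, insert
# rejection) and return labels + xyz column indices.
calpha_rows <- function(pdb) {
  at <- pdb$atom
  rows <- which(at$elety == "CA" &
                  at$type %in% c("ATOM", "HETATM") &
                  !(at$resid %in% c("HOH", "WAT")))
  if (length(rows) == 0L) stop("no Calpha atoms found")
  at <- at[rows, , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes present; renumber the structure first")
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_along(key), factor(key, levels = unique(key))),
                          function(ii) {
                            o <- at$o[ii]; o[is.na(o)] <- 1
                            alt <- as.character(at$alt[ii]); alt[is.na(alt)] <- ""
                            ii[order(-o, alt)][1L]
                          }), use.names = FALSE)
    keep <- sort(keep)
    rows <- rows[keep]
    at <- at[keep, , drop = FALSE]
  }
  chain <- as.character(at$chain); chain[is.na(chain)] <- "A"
  labels <- data.frame(chain = chain, resno = at$resno, resid = as.character(at$resid),
                       stringsAsFactors = FALSE)
  xyz_cols <- as.vector(rbind(3L * (rows - 1L) + 1L, 3L * (rows - 1L) + 2L, 3L * rows))
  list(labels = labels, xyz_cols = xyz_cols)
}

#' Load a single reference structure
#'
#' @param path PDB file.
#' @param model_index model to extract (default 1; NMR entries carry several).
#' @return a `calpha` conformer.
#' @export
load_reference <- function(path, model_index = 1L) {
  ens <- load_ensemble(path, "pdb_multimodel")
  if (model_index < 1L || model_index > n_frames(ens))
    stop("model ", model_index, " not present (file has ", n_frames(ens), ")")
  conf <- get_frame(ens, model_index)
  conf$source_id <- paste0(basename(path), " model ", model_index)
  conf
}

#' Parse a multiple sequence alignment
#'
#' @param path alignment file.
#' @param dialect `"aligned_fasta"` or `"clustal"`.
#' @return object of class `msa`: list with `names` and equal-length gapped
#'   `rows` (amino acids plus `-`).
#' @export
parse_alignment <- function(path, dialect = c("aligned_fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (dialect == "aligned_fasta") "fasta" else "clustal"
  aln <- Biostrings::readAAMultipleAlignment(path, format = fmt)
  rows <- as.character(Biostrings::unmasked(aln))
  if (length(rows) < 2L) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(rows))) != 1L) stop("ragged alignment rows")
  structure(list(names = names(rows), rows = unname(rows)), class = "msa")
}

msa_row <- function(aln, name) {
  i <- match(name, aln$names)
  if (is.na(i)) stop("unknown sequence name: ", name)
  strsplit(aln$rows[i], "")[[1L]]
}

#' Map equivalent residues of two aligned sequences
#'
#' Alignment columns where neither sequence carries a gap define the mapping;
#' its length is the number of aligned residue pairs N used throughout the
#' distance-matrix comparisons.
#'
#' @param aln an `msa`.
#' @param name_a,name_b sequence identifiers.
#' @return data.frame with 1-based ungapped positions `index_a`, `index_b`.
#' @export
map_equivalent_residues <- function(aln, name_a, name_b) {
  a <- msa_row(aln, name_a); b <- msa_row(aln, name_b)
  pos_a <- cumsum(a != "-"); pos_b <- cumsum(b != "-")
  keep <- a != "-" & b != "-"
  data.frame(index_a = pos_a[keep], index_b = pos_b[keep])
}

#' Pairwise sequence identity of two aligned rows
#'
#' Matches divided by gap-free aligned columns (the denominator is recorded in
#' the result's attributes).
#'
#' @inheritParams map_equivalent_residues
#' @return fraction in \[0, 1\] with attributes `matches` and `denominator`.
#' @export
pairwise_identity <- function(aln, name_a, name_b) {
  a <- msa_row(aln, name_a); b <- msa_row(aln, name_b)
  keep <- a != "-" & b != "-"
  n <- sum(keep)
  if (n == 0L) stop("no gap-free aligned columns between ", name_a, " and ", name_b)
  matches <- sum(a[keep] == b[keep])
  structure(matches / n, matches = matches, denominator = n,
            denominator_rule = "gap-free aligned columns")
}

#' Select binding-pocket residues by author numbering
#'
#' Resolves the strand and helix ranges (inclusive at both ends, author PDB
#' numbering per chain) against a conformer and returns a two-block selection,
#' "strand" first then "helix". The canonical pocket is a 5-residue strand
#' facing a 10-residue helix; other sizes are accepted with a warning.
#'
#' @param conf a `calpha` conformer.
#' @param strand_range,helix_range list(chain=, first=, last=).
#' @return a `residue_selection` with blocks `strand` and `helix`.
#' @export
select_binding_site <- function(conf, strand_range, helix_range) {
  res_range <- function(rng, what) {
    chain <- as.character(rng$chain %||% rng[[1L]])
    first <- as.integer(rng$first %||% rng[[2L]])
    last <- as.integer(rng$last %||% rng[[3L]])
    if (last < first) stop(what, " range is reversed")
    idx <- vapply(first:last, function(r) {
      i <- which(conf$labels$chain == chain & conf$labels$resno == r)
      if (length(i) != 1L)
        stop("residue ", chain, r, " absent from structure (", what, " range)")
      i
    }, integer(1))
    idx
  }
  s <- res_range(strand_range, "strand")
  h <- res_range(helix_range, "helix")
  if (length(intersect(s, h)) > 0L) stop("overlapping blocks")
  if (length(s) != 5L || length(h) != 10L)
    warning("non-canonical block sizes: strand ", length(s), ", helix ", length(h))
  residue_selection(c(s, h), blocks = list(strand = s, helix = h),
                    n_total = nrow(conf$xyz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis result to disk
#'
#' Matrices go to labelled TSV (full double precision, losslessly re-readable
#' with [read_matrix_tsv()]); everything else to JSON.
#'
#' @param obj matrix, or any list-like result object.
#' @param path destination file.
#' @param format `"tsv"` (matrices) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.matrix(obj)) stop("tsv format is for matrices; use json")
    df <- cbind(label = rownames(obj) %||% as.character(seq_len(nrow(obj))),
                as.data.frame(format_full(obj)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- strip_heavy(obj)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(path)
}

format_full <- function(m) {
  out <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  colnames(out) <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  out
}

# Drop large non-serialisable members before JSON output.
strip_heavy <- function(obj) {
  if (inherits(obj, "cluster_result"))
    obj$cluster_means <- lapply(obj$cluster_means, function(m) unname(m))
  if (is.list(obj)) obj <- lapply(obj, function(x) if (is.matrix(x)) unname(x) else x)
  class(obj) <- NULL
  obj
}

#' Re-read a matrix written by [write_results()]
#'
#' @param path TSV file.
#' @return numeric matrix with label dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  m <- apply(as.matrix(df[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
  rownames(m) <- df[[1L]]
  m
}
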