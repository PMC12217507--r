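#' Read a screen read-count table
#'
#' Reads a tab-separated count table — first column array identifiers, one
#' column per sequenced sample — and validates it into a count matrix with a
#' designated T0 (reference time point) sample. Every other column is
#' treated as an endpoint sample of the same screen.
#'
#' @param path Path to a TSV file with a header row.
#' @param t0 Name of the T0 sample column.
#' @return An object of class `"gi_counts"`: an integer matrix
#'   (arrays x samples, rownames = array ids) with attribute `t0`.
#' @export
read_counts <- function(path, t0) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stop("count table needs an id column, a T0 column and >= 1 endpoint column")
  ids <- df[[1L]]
  counts <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(counts), dim = dim(counts),
                                dimnames = list(ids, colnames(counts))))
  bad <- which(is.na(num) & !is.na(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  gi_counts(num, t0 = t0)
}

#' Construct a validated count matrix
#'
#' @param counts Numeric matrix of non-negative integer read counts,
#'   arrays x samples, with row and column names.
#' @param t0 Name of the T0 column.
#' @return Validated `"gi_counts"` object.
#' @export
gi_counts <- function(counts, t0) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have array ids as rownames and sample names as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate array id: ", dup[1L])
  if (anyNA(counts)) stop("missing values in count matrix")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count (%g) at array '%s', sample '%s'",
                 counts[neg[1L, , drop = FALSE]],
                 rownames(counts)[neg[1L, 1L]], colnames(counts)[neg[1L, 2L]]))
  }
  frac <- which(counts != round(counts), arr.ind = TRUE)
  if (nrow(frac)) {
    stop(sprintf("non-integer count (%g) at array '%s', sample '%s'",
                 counts[frac[1L, , drop = FALSE]],
                 rownames(counts)[frac[1L, 1L]], colnames(counts)[frac[1L, 2L]]))
  }
  if (!t0 %in% colnames(counts))
    stop("T0 sample '", t0, "' not found among samples: ",
         paste(colnames(counts), collapse = ", "))
  if (ncol(counts) < 2L) stop("need at least one endpoint sample besides T0")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in aggregate
  structure(counts, t0 = t0, class = c("gi_counts", "matrix", "array"))
}

#' Read a library annotation table
#'
#' The annotation maps each array to its target gene or gene pair and its
#' control role. Expected TSV columns: `array_id`, `gene1`, `gene2` (empty
#' for single-gene arrays), `control_class` (one of `essential_ctrl`,
#' `nonessential_ctrl`, `none`).
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame of class `"gi_annotation"` with columns `array_id`,
#'   `gene1`, `gene2` (NA for singles), `construct_class` (`"single"` or
#'   `"pair"`), `control_class`, and `target_key` (the gene symbol for
#'   singles, the canonical [pair_key()] for pairs).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  need <- c("array_id", "gene1", "gene2", "control_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  gi_annotation(df[need])
}

#' Construct a validated library annotation
#'
#' @param df data.frame with columns `array_id`, `gene1`, `gene2`,
#'   `control_class`; `gene2` is NA or empty for single-gene arrays.
#' @return Validated `"gi_annotation"` data.frame (see [read_annotation()]).
#' @export
gi_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene2[!is.na(df$gene2) & df$gene2 == ""] <- NA_character_
  dup <- df$array_id[duplicated(df$array_id)]
  if (length(dup)) stop("duplicate array id in annotation: ", dup[1L])
  if (anyNA(df$gene1) || any(df$gene1 == ""))
    stop("every array needs a non-empty gene1")
  df$control_class[is.na(df$control_class)] <- "none"
  ok <- c("essential_ctrl", "nonessential_ctrl", "none")
  bad <- setdiff(unique(df$control_class), ok)
  if (length(bad)) stop("unknown control_class token: '", bad[1L],
                        "' (expected ", paste(ok, collapse = "/"), ")")
  is_pair <- !is.na(df$gene2)
  self <- is_pair & df$gene1 == df$gene2
  if (any(self)) stop("array '", df$array_id[which(self)[1L]],
                      "' pairs a gene with itself")
  df$construct_class <- ifelse(is_pair, "pair", "single")
  df$target_key <- df$gene1
  if (any(is_pair))
    df$target_key[is_pair] <- pair_key(df$gene1[is_pair], df$gene2[is_pair])
  rownames(df) <- NULL
  class(df) <- c("gi_annotation", "data.frame")
  df
}

#' Read reference gene sets and the positive-control pair set
#'
#' `read_gene_set()` reads a plain-text file with one gene symbol per line.
#' `read_pair_set()` reads a TSV whose first two columns hold the member
#' genes of each reference synthetic-lethal pair. `reference_sets()` bundles
#' them into the validated container used throughout the package.
#'
#' @param path File path.
#' @return `read_gene_set()`: character vector; `read_pair_set()`: character
#'   vector of canonical pair keys.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' @rdname read_gene_set
#' @export
read_pair_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("pair reference set needs two gene columns")
  unique(pair_key(df[[1L]], df[[2L]]))
}

#' @rdname read_gene_set
#' @param essential,nonessential Character vectors of gene symbols used as
#'   screen quality controls (core-essential and nonessential reference
#'   roles).
#' @param sl_pairs Optional character vector of canonical pair keys (from
#'   [pair_key()]) naming positive-control synthetic-lethal pairs; required
#'   only for RdLFC scoring.
#' @return `reference_sets()`: a list of class `"gi_refs"` with elements
#'   `essential`, `nonessential`, `sl_pairs`.
#' @export
reference_sets <- function(essential = character(), nonessential = character(),
                           sl_pairs = NULL) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  both <- intersect(essential, nonessential)
  if (length(both))
    stop("gene(s) in both essential and nonessential sets: ",
         paste(utils::head(both, 3L), collapse = ", "))
  if (!is.null(sl_pairs)) sl_pairs <- unique(as.character(sl_pairs))
  structure(list(essential = essential, nonessential = nonessential,
                 sl_pairs = sl_pairs),
            class = "gi_refs")
}

#' Write and read a genetic-interaction score table
#'
#' The long-format score table (one row per pair per screen) is the
#' canonical interchange format. Missing values are written as empty cells.
#' `read_scores()` round-trips what `write_scores()` wrote.
#'
#' @param scores data.frame with columns `gene_a`, `gene_b`, `screen`,
#'   `observed_lfc`, `expected_lfc`, `dlfc`, `zlfc`, `zdlfc`, `rdlfc`,
#'   `hit_dlfc`, `hit_zdlfc`, `hit_rdlfc` (as produced by [paralog_gi()]).
#' @param path Output TSV path.
#' @export
write_scores <- function(scores, path) {
  cols <- score_columns()
  miss <- setdiff(cols, names(scores))
  if (length(miss)) stop("score table missing column(s): ", paste(miss, collapse = ", "))
  out <- scores[cols]
  for (nm in cols) {
    v <- out[[nm]]
    out[[nm]] <- if (is.numeric(v)) {
      ifelse(is.na(v), "", sprintf("%.17g", v))
    } else if (is.logical(v)) {
      ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
    } else as.character(v)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = "")
  miss <- setdiff(score_columns(), names(df))
  if (length(miss)) stop("score file missing column(s): ", paste(miss, collapse = ", "))
  for (nm in c("observed_lfc", "expected_lfc", "dlfc", "zlfc", "zdlfc", "rdlfc"))
    df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("hit_dlfc", "hit_zdlfc", "hit_rdlfc"))
    df[[nm]] <- as.logical(df[[nm]])
  df
}

score_columns <- function() {
  c("gene_a", "gene_b", "screen", "observed_lfc", "expected_lfc",
    "dlfc", "zlfc", "zdlfc", "rdlfc", "hit_dlfc", "hit_zdlfc", "hit_rdlfc")
}

#' Read a paralog percent-sequence-identity table
#'
#' Expects TSV columns `gene_a`, `gene_b`, `pct_identity_ab`,
#' `pct_identity_ba`; the two directional identities are averaged per pair
#' at load time.
#'
#' @param path TSV path.
#' @return Named numeric vector: canonical pair key -> mean percent identity
#'   in \[0, 100\].
#' @export
read_identity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("gene_a", "gene_b", "pct_identity_ab", "pct_identity_ba")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("identity table missing column(s): ", paste(miss, collapse = ", "))
  key <- pair_key(df$gene_a, df$gene_b)
  val <- (as.numeric(df$pct_identity_ab) + as.numeric(df$pct_identity_ba)) / 2
  if (any(val < 0 | val > 100, na.rm = TRUE))
    stop("percent identity outside [0, 100]")
  out <- tapply(val, key, mean)  # collapse AB/BA duplicate rows if present
  stats::setNames(as.numeric(out), names(out))
}

#' Read a gene x cell-line expression matrix (log2 TPM)
#'
#' @param path TSV: first column gene symbols, remaining columns cell lines.
#' @return Numeric matrix, genes x cell lines.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
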