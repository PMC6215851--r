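#' Construct a validated OTU table
#'
#' An OTU table is a non-negative integer count matrix with samples as rows
#' and taxa as columns. Each row is one community sample; each column one
#' operational taxonomic unit (OTU). Identifiers are opaque strings.
#'
#' @param counts Integer matrix (samples x taxa), non-negative.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#' @param taxon_ids Character vector of unique taxon identifiers; defaults to
#'   the matrix colnames.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   identifiers as dimnames.
#' @examples
#' tab <- otu_table(matrix(c(5L, 0L, 1L, 2L, 3L, 4L), nrow = 2,
#'                         dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' dim(tab)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell: sample '%s', taxon '%s' (value %s)",
      sample_ids[i[1]], taxon_ids[i[2]], format(counts[bad[1]])))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d taxa, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from a tab-separated file
#'
#' Expects a header row of identifiers and identifiers in the first column,
#' with integer counts in the body. By default samples are rows and taxa are
#' columns; many public tables are transposed, which `orientation` handles.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"samples_as_cols"`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_as_rows", "samples_as_cols")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  mat <- as.matrix(df)
  if (!is.numeric(mat))
    stop("non-numeric entries in OTU table '", path, "'")
  if (orientation == "samples_as_cols") mat <- t(mat)
  otu_table(mat)
}

#' Write an OTU table to a tab-separated file
#'
#' Samples as rows, taxa as columns, header row of taxon identifiers and a
#' leading `sample_id` column. `read_otu_table()` inverts this exactly.
#'
#' @param table An [otu_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(sample_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Plain tab-separated serialization for report tables (community-scale and
#' species-scale summaries, per-taxon classifications). An empty record set
#' produces a header-only file.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path, comments = NULL) {
  records <- as.data.frame(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-group metadata
#'
#' Two-column tab-separated file mapping `sample_id` to a group label
#' (e.g. lean / obese / overweight).
#'
#' @param path Path to a TSV with columns `sample_id` and `group` (header
#'   optional; the first two columns are used).
#' @param table Optional [otu_table]; if given, every mapped sample must
#'   exist in it.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_group_map <- function(path, table = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("group map must have two columns")
  out <- tibble::tibble(sample_id = as.character(df[[1]]),
                        group = as.character(df[[2]]))
  validate_group_map(out, table)
}

#' @rdname read_group_map
#' @param groups A data frame with columns `sample_id` and `group`.
#' @export
validate_group_map <- function(groups, table = NULL) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  if (anyDuplicated(groups$sample_id))
    stop("duplicate sample_id in group map")
  if (!is.null(table)) {
    missing <- setdiff(groups$sample_id, rownames(table))
    if (length(missing))
      stop("group map references unknown samples: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  groups
}

#' Convert one sample of an OTU table to a species-abundance distribution
#'
#' Drops zero-count taxa, sorts abundances in descending order and computes
#' the abundance-multiplicity summary phi (number of species at each
#' abundance value). The SAD D = (n_1, ..., n_S) is the data unit of the
#' community-level neutrality machinery.
#'
#' @param table An [otu_table].
#' @param sample_id Sample identifier (row of the table).
#' @return A `community_sad`: list with `abundances` (descending positive
#'   integers), `J` (total reads), `S` (species count), `phi` (named integer
#'   vector, abundance value -> number of species), `sample_id`.
#' @examples
#' tab <- otu_table(matrix(c(0L, 5L, 1L, 1L), nrow = 1,
#'                         dimnames = list("s1", paste0("t", 1:4))))
#' sample_to_sad(tab, "s1")
#' @export
sample_to_sad <- function(table, sample_id) {
  stopifnot(inherits(table, "otu_table"))
  if (!sample_id %in% rownames(table))
    stop("sample '", sample_id, "' not found")
  x <- unclass(table)[sample_id, ]
  x <- x[x > 0]
  if (!length(x))
    stop("sample '", sample_id, "' has no reads (empty community)")
  community_sad(sort(as.integer(x), decreasing = TRUE), sample_id = sample_id)
}

#' Construct a species-abundance distribution from raw abundances
#'
#' @param abundances Positive integer vector (any order; sorted internally).
#' @param sample_id Optional identifier carried along for reporting.
#' @return A `community_sad` (see [sample_to_sad]).
#' @export
community_sad <- function(abundances, sample_id = NA_character_) {
  abundances <- as.integer(abundances)
  if (!length(abundances) || any(abundances < 1))
    stop("abundances must be a non-empty vector of positive integers")
  abundances <- sort(abundances, decreasing = TRUE)
  tab <- table(abundances)
  phi <- as.integer(tab)
  names(phi) <- names(tab)
  structure(list(abundances = abundances,
                 J = sum(abundances),
                 S = length(abundances),
                 phi = phi,
                 sample_id = sample_id),
            class = "community_sad")
}

#' @export
print.community_sad <- function(x, ...) {
  cat(sprintf("Community SAD%s: J = %d reads, S = %d species\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$J, x$S))
  cat("abundances:", paste(utils::head(x$abundances, 12), collapse = " "),
      if (x$S > 12) "..." else "", "\n")
  invisible(x)
}
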