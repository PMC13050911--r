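#' Construct a count table
#'
#' A `count_table` holds taxon x sample read counts for one microbial domain
#' (bacteria or fungi) at one taxonomic level, together with a lineage string
#' per taxon.  It is the universal input of the pipeline: diversity, network
#' and core-taxon stages all start from one (or a pair) of these.
#'
#' @param counts numeric matrix of non-negative integer read counts, taxa as
#'   rows and samples as columns; dimnames give taxon and sample identifiers.
#' @param taxonomy character vector of rank-delimited lineage strings, one per
#'   taxon (Greengenes-style `"k__...;p__...;...;g__..."`; unprefixed strings
#'   are accepted positionally).  Defaults to `"unclassified"` everywhere.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param level taxonomic level of the rows: `"OTU"`, `"genus"` or `"phylum"`.
#'
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `taxonomy`, `domain` and `level`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ct <- count_table(m, domain = "bacteria")
#' taxon_ids(ct)
#' @export
count_table <- function(counts, taxonomy = NULL,
                        domain = c("bacteria", "fungi"),
                        level = c("OTU", "genus", "phylum")) {
  domain <- match.arg(domain)
  level <- match.arg(level)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers (reads)")
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) taxonomy <- rep("unclassified", nrow(counts))
  if (length(taxonomy) != nrow(counts))
    stop("taxonomy must have one entry per taxon")
  taxonomy <- as.character(taxonomy)
  taxonomy[is.na(taxonomy) | taxonomy == ""] <- "unclassified"
  structure(list(counts = counts, taxonomy = taxonomy,
                 domain = domain, level = level),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d %s-level taxa x %d samples (%s)\n",
              nrow(x$counts), x$level, ncol(x$counts), x$domain))
  cat(sprintf("  total reads: %.0f; library sizes %d-%d\n",
              sum(as.numeric(x$counts)),
              min(colSums(x$counts)), max(colSums(x$counts))))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
library_sizes <- function(x) colSums(x$counts)

#' Read a taxon x sample count table from TSV
#'
#' Expects a header row of sample identifiers, a first column of taxon
#' identifiers, and an optional trailing `taxonomy` column holding lineage
#' strings.  Ragged rows, duplicated identifiers and negative or non-integer
#' counts are rejected with informative errors.
#'
#' @param path path to a tab-separated file.
#' @inheritParams count_table
#' @return a [count_table].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, domain = c("bacteria", "fungi"),
                             level = c("OTU", "genus", "phylum")) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("count table needs at least one sample column")
  taxa <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric count encountered in ", path)
  dimnames(m) <- list(taxa, names(df))
  count_table(m, taxonomy = taxonomy, domain = domain, level = level)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; round-trips are value-identical.
#'
#' @param x a [count_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(taxon_id = taxon_ids(x), x$counts,
                   taxonomy = x$taxonomy, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample column is divided by its library size.  Samples with zero
#' reads are kept as all-zero columns (with a warning) rather than dropped,
#' so downstream stages can decide how to treat them.
#'
#' @param x a [count_table] with at least one sample with positive library.
#' @return an object of class `rel_abundance_table`: like a `count_table`
#'   but with a numeric `values` matrix of proportions (columns sum to 1 for
#'   samples with any reads).
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "count_table"))
  if (ncol(x$counts) == 0L || nrow(x$counts) == 0L) stop("empty count table")
  libs <- colSums(x$counts)
  if (all(libs == 0)) stop("no sample has a positive library size")
  if (any(libs == 0))
    warning("all-zero sample(s) kept as zero columns: ",
            paste(colnames(x$counts)[libs == 0], collapse = ", "))
  vals <- sweep(x$counts, 2L, pmax(libs, 1L), "/")
  vals[, libs == 0] <- 0
  structure(list(values = vals, taxonomy = x$taxonomy,
                 domain = x$domain, level = x$level),
            class = "rel_abundance_table")
}

#' @export
print.rel_abundance_table <- function(x, ...) {
  cat(sprintf("rel_abundance_table: %d %s-level taxa x %d samples (%s)\n",
              nrow(x$values), x$level, ncol(x$values), x$domain))
  invisible(x)
}

.tax_ranks <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__",
                species = "s__")

# Extract one rank from a lineage string; prefixed fields win, otherwise the
# field at the rank's position is used. Unparseable -> "unclassified".
.parse_rank <- function(taxonomy, rank) {
  prefix <- .tax_ranks[[rank]]
  pos <- match(rank, names(.tax_ranks))
  vapply(strsplit(taxonomy, ";", fixed = TRUE), function(fields) {
    fields <- trimws(fields)
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) {
      out <- sub(prefix, "", hit[1L], fixed = TRUE)
    } else if (!any(grepl("__", fields, fixed = TRUE)) &&
               length(fields) >= pos) {
      out <- fields[pos]
    } else {
      out <- ""
    }
    if (is.na(out) || out == "") "unclassified" else out
  }, character(1L))
}

#' Aggregate a count table at a higher taxonomic rank
#'
#' Counts are summed over taxa sharing the same label at the requested rank;
#' taxa whose lineage cannot be parsed at that rank are pooled under
#' `"unclassified"`.  Per-sample library sizes are conserved.
#'
#' @param x a [count_table].
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return a [count_table] at the requested level (level is recorded as
#'   `"genus"` or `"phylum"` when those ranks are requested, `"OTU"` otherwise).
#' @export
aggregate_level <- function(x, rank) {
  stopifnot(inherits(x, "count_table"))
  if (!rank %in% names(.tax_ranks))
    stop("unknown rank '", rank, "'; valid ranks: ",
         paste(names(.tax_ranks), collapse = ", "))
  labels <- .parse_rank(x$taxonomy, rank)
  agg <- rowsum(x$counts, group = labels, reorder = TRUE)
  storage.mode(agg) <- "integer"
  # keep the lineage up to the requested rank for each aggregated row
  pos <- match(rank, names(.tax_ranks))
  lineage <- vapply(rownames(agg), function(lab) {
    i <- which(labels == lab)[1L]
    fields <- trimws(strsplit(x$taxonomy[i], ";", fixed = TRUE)[[1L]])
    if (lab == "unclassified") return("unclassified")
    paste(fields[seq_len(min(pos, length(fields)))], collapse = ";")
  }, character(1L))
  level <- if (rank %in% c("genus", "phylum")) rank else "OTU"
  count_table(agg, taxonomy = unname(lineage), domain = x$domain,
              level = level)
}

#' Read and validate a sample metadata table
#'
#' The metadata TSV must have columns `sample_id`, `species`, `treatment`
#' (`open`/`bagging`), `pollination` (`self`/`cross`) and `replicate`.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with one validated row per sample.
#' @export
read_sample_frame <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

#' @rdname read_sample_frame
#' @param meta a data.frame with the columns listed above.
#' @export
validate_sample_frame <- function(meta) {
  need <- c("sample_id", "species", "treatment", "pollination", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  for (col in c("species", "treatment", "pollination")) {
    bad <- is.na(meta[[col]]) | meta[[col]] == ""
    if (any(bad))
      stop("missing ", col, " for sample ", meta$sample_id[bad][1L])
  }
  meta$replicate <- as.integer(meta$replicate)
  meta
}

#' Assign samples to pollination-type x treatment groups
#'
#' Samples are classified into the four experimental groups used throughout
#' the pipeline: `Self_open`, `Self_bagging`, `Cross_open`, `Cross_bagging`
#' (pollination type of the host crossed with the insect-exclusion
#' treatment).
#'
#' @param meta a sample metadata data.frame (see [read_sample_frame()]).
#' @return named character vector mapping `sample_id` to group; group sizes
#'   are attached as attribute `"sizes"`.
#' @examples
#' meta <- data.frame(sample_id = c("a", "b"), species = c("LA", "CA"),
#'                    treatment = c("open", "bagging"),
#'                    pollination = c("cross", "self"), replicate = 1:2)
#' assign_groups(meta)
#' @export
assign_groups <- function(meta) {
  meta <- validate_sample_frame(meta)
  badp <- !meta$pollination %in% c("self", "cross")
  if (any(badp))
    stop("unknown pollination '", meta$pollination[badp][1L],
         "' for sample ", meta$sample_id[badp][1L])
  badt <- !meta$treatment %in% c("open", "bagging")
  if (any(badt))
    stop("unknown treatment '", meta$treatment[badt][1L],
         "' for sample ", meta$sample_id[badt][1L])
  grp <- paste0(ifelse(meta$pollination == "self", "Self", "Cross"),
                "_", meta$treatment)
  names(grp) <- meta$sample_id
  attr(grp, "sizes") <- table(grp)
  grp
}
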