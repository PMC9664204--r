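#' Construct and validate a gene table
#'
#' A gene table is the substrate of all synteny and paralogon analyses: one
#' row per gene of one species, with a family assignment and genomic
#' coordinates. Coordinates are 0-based half-open throughout the package;
#' format conversions happen only at the file boundary.
#'
#' @param df data.frame with columns `gene_id`, `family_id`, `chromosome`,
#'   `start`, `end`, `strand` (one of `+`, `-`, `.`) and `status`
#'   (`coding` or `pseudogene`).
#' @param species Species name the table belongs to.
#' @return A `gene_table` (a sorted data.frame with a `species` attribute).
#' @export
gene_table <- function(df, species) {
  required <- c("gene_id", "family_id", "chromosome", "start", "end",
                "strand", "status")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[required]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- which(!(df$start < df$end) | df$start < 0 |
                 is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("invalid coordinates (need 0 <= start < end) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop("duplicate gene_id at row(s): ", paste(dup, collapse = ", "),
         " (", paste(unique(df$gene_id[dup]), collapse = ", "), ")",
         call. = FALSE)
  bad_strand <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad_strand))
    stop("invalid strand at row(s): ", paste(bad_strand, collapse = ", "),
         call. = FALSE)
  bad_status <- which(!df$status %in% c("coding", "pseudogene"))
  if (length(bad_status))
    stop("invalid status at row(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, species = species, class = c("gene_table", "data.frame"))
}

#' Read a gene table from disk
#'
#' Two dialects are supported. `"bed"` is a BED-like 7-column TSV
#' (`chromosome  start  end  gene_id  family_id  strand  status`) with
#' 0-based half-open coordinates and no header (comment lines starting with
#' `#` are skipped). `"gff3"` is a GFF3 subset: rows of type `gene` with
#' `ID=` and `family=` (and optional `status=`) attributes; GFF3 1-based
#' closed coordinates are converted to the internal 0-based half-open
#' convention on read.
#'
#' @param path File path.
#' @param species Species name to attach to the table.
#' @param dialect `"bed"` or `"gff3"`.
#' @return A sorted [gene_table()].
#' @export
read_gene_table <- function(path, species, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty gene table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bed") {
    nf <- lengths(fields)
    if (any(nf != 7L))
      stop("BED-like dialect needs 7 tab-separated columns; offending row(s): ",
           paste(which(nf != 7L), collapse = ", "), call. = FALSE)
    m <- do.call(rbind, fields)
    df <- data.frame(chromosome = m[, 1],
                     start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
                     gene_id = m[, 4], family_id = m[, 5],
                     strand = m[, 6], status = m[, 7])
  } else {
    nf <- lengths(fields)
    if (any(nf != 9L))
      stop("GFF3 subset needs 9 tab-separated columns; offending row(s): ",
           paste(which(nf != 9L), collapse = ", "), call. = FALSE)
    m <- do.call(rbind, fields)
    keep <- m[, 3] == "gene"
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) stop("no rows of type 'gene' in ", path, call. = FALSE)
    attr_field <- function(attrs, key) {
      out <- vapply(strsplit(attrs, ";", fixed = TRUE), function(kv) {
        kv <- trimws(kv)
        hit <- kv[startsWith(kv, paste0(key, "="))]
        if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
      }, character(1))
      out
    }
    ids <- attr_field(m[, 9], "ID")
    fam <- attr_field(m[, 9], "family")
    status <- attr_field(m[, 9], "status")
    status[is.na(status)] <- "coding"
    if (anyNA(ids))
      stop("GFF3 rows without ID attribute: row(s) ",
           paste(which(is.na(ids)), collapse = ", "), call. = FALSE)
    if (anyNA(fam))
      stop("GFF3 rows without family attribute: row(s) ",
           paste(which(is.na(fam)), collapse = ", "), call. = FALSE)
    # GFF3 1-based closed -> 0-based half-open
    df <- data.frame(chromosome = m[, 1],
                     start = as.numeric(m[, 4]) - 1, end = as.numeric(m[, 5]),
                     gene_id = ids, family_id = fam,
                     strand = m[, 7], status = status)
  }
  gene_table(df, species)
}

#' Write a gene table to disk
#'
#' @param table A [gene_table()].
#' @param path Output path.
#' @param dialect `"bed"` (0-based half-open) or `"gff3"` (converted back to
#'   1-based closed on write, so read/write round-trips exactly).
#' @export
write_gene_table <- function(table, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   table$chromosome, as.integer(table$start),
                   as.integer(table$end), table$gene_id, table$family_id,
                   table$strand, table$status)
  } else {
    out <- sprintf("%s\tohnologr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%s;status=%s",
                   table$chromosome, as.integer(table$start) + 1L,
                   as.integer(table$end), table$strand, table$gene_id,
                   table$family_id, table$status)
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.gene_table <- function(x, ...) {
  cat("Gene table for", attr(x, "species"), "-", nrow(x), "genes on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  NextMethod()
}
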