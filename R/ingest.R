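#' Read an InterProScan-style gene annotation table
#'
#' Expects a tab-separated file (or connection) with a header row and the
#' columns `organism_id`, `gene_id`, `length_aa` and `ipr_accessions`
#' (semicolon-separated signature accessions; empty means no match).
#' Multiple rows for the same gene within an organism — the usual shape of
#' scanner output, one row per matched signature — are merged into a single
#' record whose signature set is the union over rows.
#'
#' @param path path to a TSV file, or a connection.
#' @return data frame with one row per gene: `organism_id`, `gene_id`,
#'   `length` (integer residues) and `signatures` (semicolon-joined, sorted,
#'   de-duplicated accession string).
#' @export
read_gene_annotations <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = TRUE, quote = "", comment.char = "")
  required <- c("organism_id", "gene_id", "length_aa", "ipr_accessions")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("gene annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(organism_id = character(), gene_id = character(),
                      length = integer(), signatures = character(),
                      stringsAsFactors = FALSE))
  len <- suppressWarnings(as.numeric(raw$length_aa))
  bad <- which(is.na(len) | len != floor(len) | len < 1)
  if (length(bad))
    stop(sprintf("non-integer or missing gene length at data row %d (value '%s')",
                 bad[1], raw$length_aa[bad[1]]), call. = FALSE)
  rec <- data.frame(
    organism_id = trimws2(raw$organism_id),
    gene_id = trimws2(raw$gene_id),
    length = as.integer(len),
    signatures = trimws2(raw$ipr_accessions),
    stringsAsFactors = FALSE
  )
  key <- paste(rec$organism_id, rec$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    parts <- split(seq_len(nrow(rec)), factor(key, levels = unique(key)))
    rec <- do.call(rbind, lapply(parts, function(idx) {
      lens <- unique(rec$length[idx])
      if (length(lens) > 1L)
        stop(sprintf("conflicting lengths (%s) for gene '%s' of organism '%s'",
                     paste(lens, collapse = ", "),
                     rec$gene_id[idx[1]], rec$organism_id[idx[1]]),
             call. = FALSE)
      sigs <- sort(split_accessions(rec$signatures[idx]))
      data.frame(organism_id = rec$organism_id[idx[1]],
                 gene_id = rec$gene_id[idx[1]],
                 length = lens,
                 signatures = paste(sigs[nzchar(sigs)], collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    rownames(rec) <- NULL
  } else {
    rec$signatures <- vapply(rec$signatures, function(s) {
      sigs <- sort(split_accessions(s))
      paste(sigs[nzchar(sigs)], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  rec
}

# accept gene tables in either the parsed dialect (length, signatures) or
# the on-disk dialect (length_aa, ipr_accessions)
as_gene_records <- function(genes) {
  if (!"length" %in% names(genes) && "length_aa" %in% names(genes))
    genes$length <- as.integer(genes$length_aa)
  if (!"signatures" %in% names(genes) && "ipr_accessions" %in% names(genes))
    genes$signatures <- genes$ipr_accessions
  need <- c("organism_id", "gene_id", "length", "signatures")
  missing <- setdiff(need, names(genes))
  if (length(missing))
    stop("gene table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  genes
}

#' Retain genes at or below the size cutoff
#'
#' The census targets small PECs: genes encoding proteins of more than
#' `cutoff` residues are excluded, so a 200-residue gene is kept and a
#' 201-residue gene is dropped at the default cutoff. Input order is
#' preserved and the operation is idempotent.
#'
#' @param records gene data frame as from [read_gene_annotations()].
#' @param cutoff integer, residues (default 200).
#' @return the filtered data frame.
#' @export
apply_length_filter <- function(records, cutoff = 200L) {
  cutoff <- check_count(cutoff, "cutoff", min = 1L)
  records <- as_gene_records(records)
  records[records$length <= cutoff, , drop = FALSE]
}

#' Read an organism metadata table
#'
#' Accepts a tab-separated table with columns `organism_id` and `domain`,
#' and optionally `phylum`, `class`, `o2`, `temperature` and `ph`. Domain
#' values other than Archaea/Bacteria/Eukaryota are mapped to `"unknown"`;
#' growth labels are kept verbatim here and only normalized by the niche
#' functions.
#'
#' @param path path to a TSV file, or a connection.
#' @return data frame of organism metadata.
#' @export
read_organism_metadata <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    quote = "", comment.char = "")
  required <- c("organism_id", "domain")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("metadata table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(
    organism_id = trimws2(raw$organism_id),
    domain = canonical_domain(raw$domain),
    phylum = if ("phylum" %in% names(raw)) trimws2(raw$phylum) else NA_character_,
    class = if ("class" %in% names(raw)) trimws2(raw$class) else NA_character_,
    o2 = if ("o2" %in% names(raw)) trimws2(raw$o2) else NA_character_,
    temperature = if ("temperature" %in% names(raw)) trimws2(raw$temperature) else NA_character_,
    ph = if ("ph" %in% names(raw)) suppressWarnings(as.numeric(raw$ph)) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$organism_id)))
    stop("metadata table contains an empty organism_id", call. = FALSE)
  dup <- out$organism_id[duplicated(out$organism_id)]
  if (length(dup))
    stop("duplicate organism_id in metadata: ", dup[1], call. = FALSE)
  out
}

canonical_domain <- function(x) {
  x <- trimws2(x)
  ifelse(x %in% c("Archaea", "Bacteria", "Eukaryota"), x, "unknown")
}

#' Read a pre-counted census table (supplementary-dataset mode)
#'
#' Ingests a table that already carries per-organism family counts together
#' with taxonomy and niche metadata — the shape of a published supplementary
#' census sheet. Because such sheets vary in layout, `mapping` binds the
#' canonical fields to the file's column names without code changes.
#'
#' @param path path to a delimited file, or a connection.
#' @param mapping named character vector or list mapping canonical fields
#'   (`organism_id`, `n_fd4`, `n_fd2`, `n_fld`, and optionally `n_7fe`,
#'   `domain`, `phylum`, `class`, `o2`, `temperature`, `ph`) to column names
#'   in the file. Defaults to the identity mapping.
#' @param sep field separator (default tab).
#' @return a `pec_census` data frame (see [build_census()]).
#' @export
read_supplementary_census <- function(path, mapping = NULL, sep = "\t") {
  defaults <- c(organism_id = "organism_id", n_fd4 = "n_fd4", n_fd2 = "n_fd2",
                n_fld = "n_fld", n_7fe = "n_7fe", domain = "domain",
                phylum = "phylum", class = "class", o2 = "o2",
                temperature = "temperature", ph = "ph")
  map <- defaults
  if (!is.null(mapping)) {
    mapping <- unlist(mapping)
    unknown <- setdiff(names(mapping), names(defaults))
    if (length(unknown))
      stop("unknown census field(s) in column mapping: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    map[names(mapping)] <- mapping
  }
  raw <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    quote = "", comment.char = "", check.names = FALSE)
  need <- c("organism_id", "n_fd4", "n_fd2", "n_fld")
  missing <- setdiff(unname(map[need]), names(raw))
  if (length(missing))
    stop("census table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  get_col <- function(field) if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NULL

  id <- trimws2(get_col("organism_id"))
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate organism id in census table: ", dup[1], call. = FALSE)

  count_col <- function(field) {
    x <- get_col(field)
    if (is.null(x)) return(rep(0L, length(id)))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad))
      stop(sprintf("invalid count '%s' in column '%s' at data row %d",
                   x[bad[1]], map[[field]], bad[1]), call. = FALSE)
    as.integer(v)
  }
  n_fd4 <- count_col("n_fd4"); n_fd2 <- count_col("n_fd2")
  n_fld <- count_col("n_fld"); n_7fe <- count_col("n_7fe")
  if (any(n_7fe > n_fd4))
    stop("7Fe count exceeds the [4Fe-4S] count for organism: ",
         id[which(n_7fe > n_fd4)[1]], call. = FALSE)

  chr_col <- function(field, default = NA_character_) {
    x <- get_col(field)
    if (is.null(x)) rep(default, length(id)) else trimws2(x)
  }
  ph_raw <- get_col("ph")
  census <- data.frame(
    organism_id = id,
    domain = canonical_domain(chr_col("domain", "unknown")),
    phylum = chr_col("phylum"),
    class = chr_col("class"),
    o2 = chr_col("o2"),
    temperature = chr_col("temperature"),
    ph = if (is.null(ph_raw)) NA_real_ else suppressWarnings(as.numeric(ph_raw)),
    n_fd4 = n_fd4, n_fd2 = n_fd2, n_fld = n_fld, n_7fe = n_7fe,
    total = n_fd4 + n_fd2 + n_fld,
    stringsAsFactors = FALSE
  )
  as_pec_census(census)
}
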