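# Genomic predictors: duplicated-gene counts from all-vs-all homology hit
# tables, and per-category gene counts (NOGF) against a declared functional
# catalogue.

#' Count duplicated genes from homology hits
#'
#' A gene is called duplicated iff it takes part -- as query or subject --
#' in at least one same-species, non-self hit with `E < e_max` and query
#' coverage `> cov_min_pct` (both strict). A passing hit marks both of its
#' genes: the search is directional but duplication is a symmetric property.
#'
#' @param hits Data frame with columns `species`, `query`, `subject`,
#'   `evalue`, `coverage` (percent, 0-100), and optionally
#'   `subject_species` for cross-species hits (rows with
#'   `subject_species != species` are ignored).
#' @param e_max E-value threshold (exclusive), default `1e-5`.
#' @param cov_min_pct Query-coverage threshold in percent (exclusive),
#'   default 30.
#' @return Named integer vector: number of distinct duplicated genes per
#'   species present in `hits` (0 for species with no passing hit).
#' @examples
#' h <- data.frame(species = "sp1", query = c("g1", "g3"),
#'                 subject = c("g2", "g4"),
#'                 evalue = c(1e-6, 1e-3), coverage = c(40, 90))
#' count_duplicated_genes(h)  # only the first hit passes: g1 and g2
#' @export
count_duplicated_genes <- function(hits, e_max = 1e-5, cov_min_pct = 30) {
  need <- c("species", "query", "subject", "evalue", "coverage")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(hits$evalue) | hits$evalue < 0 |
                 !is.finite(hits$coverage) |
                 hits$coverage < 0 | hits$coverage > 100 |
                 is.na(hits$query) | is.na(hits$subject))
  if (length(bad))
    stop("malformed hit row(s): ", paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  same_sp <- if ("subject_species" %in% names(hits))
    hits$subject_species == hits$species else TRUE
  pass <- same_sp &
    hits$query != hits$subject &
    hits$evalue < e_max &
    hits$coverage > cov_min_pct
  out <- integer(0)
  species <- unique(hits$species)
  out <- vapply(species, function(sp) {
    sel <- pass & hits$species == sp
    length(unique(c(hits$query[sel], hits$subject[sel])))
  }, integer(1))
  names(out) <- species
  out
}

#' Read a homology hit table (BLAST tabular dialect)
#'
#' Reads the 12-column tabular format (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), optionally
#' extended with extra columns. Query coverage is taken from a `qcovs`
#' column when present, or computed as `100 * length / qlen` when a `qlen`
#' column is present; plain 12-column tables carry neither and are rejected
#' because the duplicated-gene filter needs coverage.
#'
#' @param path File path (plain TSV; a header line starting with `qseqid`
#'   or `#` is detected and honoured, otherwise standard column names are
#'   assumed for the first 12 columns and any extras must be named via
#'   `extra_cols`).
#' @param species Species label to attach to every row.
#' @param extra_cols Names for columns beyond the 12 standard ones when the
#'   file has no header (default `"qcovs"`).
#' @return Data frame with columns `species`, `query`, `subject`, `evalue`,
#'   `coverage`, ready for [count_duplicated_genes()].
#' @export
read_blast_hits <- function(path, species, extra_cols = "qcovs") {
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- readLines(path, n = 1L)
  has_header <- grepl("^#?\\s*qseqid", first)
  d <- utils::read.table(path, header = has_header, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  if (!has_header) {
    if (ncol(d) < 12L) stop("hit table has fewer than 12 columns")
    names(d) <- c(std, extra_cols)[seq_len(ncol(d))]
  }
  names(d) <- sub("^#\\s*", "", names(d))
  if ("qcovs" %in% names(d)) {
    cov <- d$qcovs
  } else if ("qlen" %in% names(d)) {
    cov <- 100 * d$length / d$qlen
  } else {
    stop("no query coverage obtainable: supply a 'qcovs' or 'qlen' column")
  }
  data.frame(species = species, query = d$qseqid, subject = d$sseqid,
             evalue = d$evalue, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Count genes per functional category (NOGF)
#'
#' `NOGF[s, c]` is the number of distinct genes of species `s` annotated to
#' category `c`. A gene carrying `k` category annotations contributes 1 to
#' each of the `k` categories; duplicate (gene, category) records are
#' counted once; catalogue categories absent from a species score 0.
#'
#' @param map Data frame with columns `species`, `gene`, `category`.
#' @param catalogue Character vector of all admissible category labels.
#' @return Integer matrix, species x catalogue.
#' @export
count_nogf <- function(map, catalogue) {
  miss <- setdiff(c("species", "gene", "category"), names(map))
  if (length(miss))
    stop("gene-function map missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(catalogue)) stop("catalogue labels must be unique")
  unknown <- setdiff(unique(map$category), catalogue)
  if (length(unknown))
    stop("categories outside the catalogue: ",
         paste(head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) ", ..." else "")
  map <- unique(map[c("species", "gene", "category")])
  tab <- table(factor(map$species, levels = sort(unique(map$species))),
               factor(map$category, levels = catalogue))
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Read a gene-to-category map
#'
#' Two-column-per-species TSV contract: columns `species`, `gene`,
#' `category`.
#'
#' @param path File path.
#' @return Data frame with those three columns.
#' @export
read_gene_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "gene", "category"), names(d))
  if (length(miss))
    stop("gene-function map missing column(s): ",
         paste(miss, collapse = ", "))
  d
}
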