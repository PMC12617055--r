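#' Read a gene x sample count matrix
#'
#' TSV layout: first column gene ids, remaining columns one per sample.
#' MTX layout: a MatrixMarket triplet file plus sidecar row (gene) and
#' column (sample) id files, one id per line; by default
#' `<path>.rownames` / `<path>.colnames`.
#'
#' @param path Path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path,samples_path Sidecar id files for `format = "mtx"`.
#' @return Integer matrix (genes x samples) with dimnames; validated to be
#'   non-negative, integral, with unique ids.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes_path = paste0(path, ".rownames"),
                        samples_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    dimnames(mat) <- list(gene_ids, colnames(tab)[-1])
  } else {
    m <- Matrix::readMM(path)
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    mat <- as.matrix(m)
    dimnames(mat) <- list(gene_ids, sample_ids)
  }
  validate_counts(mat)
}

#' Validate a count matrix
#'
#' @param counts Numeric matrix, genes x samples, with dimnames.
#' @return The matrix with integer storage, invisibly checked.
#' @export
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "counts must be non-negative integers; first offender: gene '%s', sample '%s' (value %s); %d offending cell(s) total",
      rownames(counts)[i], colnames(counts)[j], format(counts[i, j]), nrow(bad)))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a sample table
#'
#' @param path TSV with columns `sample_id`, `species`, `sex`, `tissue`,
#'   `replicate`.
#' @param counts Optional count matrix to validate sample ids against.
#' @return Tibble.
#' @export
read_samples <- function(path, counts = NULL) {
  tab <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                             stringsAsFactors = FALSE))
  validate_samples(tab, counts)
}

validate_samples <- function(samples, counts = NULL) {
  need <- c("sample_id", "species", "sex", "tissue", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) stop("sample table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!all(samples$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'; found: ",
         paste(setdiff(unique(samples$sex), c("male", "female")), collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample table")
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), samples$sample_id)
    if (length(miss) > 0)
      stop("samples present in counts but missing from sample table: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  tibble::as_tibble(samples)
}

#' Read a gene annotation
#'
#' BED-like TSV dialect: columns `gene_id`, `chromosome`, `start`, `end`
#' (0-based half-open) and optionally `length`, `is_mitochondrial`,
#' `is_placed`. GFF3 dialect: `gene` features are extracted and their
#' 1-based inclusive coordinates converted to 0-based half-open; the gene id
#' is taken from the `ID` attribute.
#'
#' Missing flags are filled from chromosome-name patterns: a chromosome
#' matching `mito_pattern` marks its genes mitochondrial; one matching
#' `unplaced_pattern` marks them unplaced.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param counts Optional count matrix; every counted gene must be annotated.
#' @param mito_pattern,unplaced_pattern Regexes (case-insensitive) applied to
#'   chromosome names when explicit flag columns are absent.
#' @return Tibble `(gene_id, chromosome, start, end, length,
#'   is_mitochondrial, is_placed)`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "gff3"), counts = NULL,
                            mito_pattern = "^(chr)?MT?$|mito",
                            unplaced_pattern = "scaffold|unplaced|contig") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                               stringsAsFactors = FALSE))
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("the gff3 dialect requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    tab <- tibble::tibble(
      gene_id = as.character(gr$ID),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr)
    )
  }
  validate_annotation(tab, counts, mito_pattern, unplaced_pattern)
}

validate_annotation <- function(tab, counts = NULL,
                                mito_pattern = "^(chr)?MT?$|mito",
                                unplaced_pattern = "scaffold|unplaced|contig") {
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("annotation missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in annotation")
  if (!("length" %in% names(tab))) tab$length <- tab$end - tab$start
  if (any(tab$length <= 0))
    stop("gene(s) with length <= 0: ",
         paste(utils::head(tab$gene_id[tab$length <= 0], 5), collapse = ", "))
  if (!("is_mitochondrial" %in% names(tab)))
    tab$is_mitochondrial <- grepl(mito_pattern, tab$chromosome, ignore.case = TRUE)
  if (!("is_placed" %in% names(tab)))
    tab$is_placed <- !grepl(unplaced_pattern, tab$chromosome, ignore.case = TRUE)
  if (!is.null(counts)) {
    missing_genes <- setdiff(rownames(counts), tab$gene_id)
    if (length(missing_genes) > 0)
      stop("counted gene(s) missing from annotation: ",
           paste(utils::head(missing_genes, 10), collapse = ", "),
           if (length(missing_genes) > 10) sprintf(" (and %d more)", length(missing_genes) - 10) else "")
  }
  tibble::as_tibble(tab[, c("gene_id", "chromosome", "start", "end", "length",
                            "is_mitochondrial", "is_placed")])
}

#' Read per-species sex-system declarations
#'
#' @param path TSV with columns `species`, `heterogamety` (XY/ZW/unknown) and
#'   `sex_linked_chromosomes` (comma-separated, empty for unknown).
#' @return Tibble with `sex_linked_chromosomes` as a list column.
#' @export
read_sex_systems <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = NULL)
  validate_sex_systems(tibble::tibble(
    species = tab$species,
    heterogamety = tab$heterogamety,
    sex_linked_chromosomes = lapply(strsplit(as.character(tab$sex_linked_chromosomes), ","),
                                    function(x) trimws(x[nzchar(trimws(x))]))
  ))
}

validate_sex_systems <- function(tab) {
  if (!all(tab$heterogamety %in% c("XY", "ZW", "unknown")))
    stop("heterogamety must be XY, ZW or unknown")
  bad <- tab$heterogamety == "unknown" &
    vapply(tab$sex_linked_chromosomes, length, 1L) > 0
  if (any(bad))
    stop("species with unknown heterogamety must not list sex-linked chromosomes: ",
         paste(tab$species[bad], collapse = ", "))
  tibble::as_tibble(tab)
}

#' Write a count matrix as TSV
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables and a machine-readable run summary
#'
#' Every tibble in `tables` is written as `<name>.tsv` with a deterministic
#' column order (as stored); list columns are flattened to comma-separated
#' strings. A `summary.json` captures run metadata.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param meta Named list of run metadata (seed, thresholds, ...) stored in
#'   `summary.json` alongside package version and file names.
#' @return Invisible character vector of files written.
#' @export
write_results <- function(tables, out_dir, meta = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (cn in names(tab)) {
      if (is.list(tab[[cn]]))
        tab[[cn]] <- vapply(tab[[cn]], paste, "", collapse = ",")
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  summary <- c(meta, list(package_version = as.character(utils::packageVersion("sexbiasr")),
                          files = basename(paths)))
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}

#' Write a simulated dataset in the formats the readers accept
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory.
#' @return Invisible vector of files written.
#' @export
write_dataset <- function(sim, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  cp <- file.path(out_dir, "counts.tsv")
  write_counts(sim$counts, cp)
  files <- write_results(
    list(samples = sim$samples, annotation = sim$annotation,
         truth_effects = sim$truth$effects,
         truth_size_factors = sim$truth$size_factors),
    out_dir, meta = list(seed = sim$config$seed, n_genes = sim$config$n_genes))
  invisible(c(cp, files))
}
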