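# Domain containers (plain S3 lists) and readers/writers for the text
# formats the pipeline consumes: FASTA, gene x sample log-ratio matrices,
# BED5 read positions, per-gene conservation tracks and score tables.

VALID_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and maps U to T. All internal sequence matching is done on this
#' normalized form, so RNA and DNA inputs are interchangeable.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector, uppercase, U replaced by T.
#' @export
normalize_seq <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

check_alphabet <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTUN]", toupper(seq))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,U,N}: %s",
                 what, substr(toupper(seq[bad][1]), 1, 40)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a small RNA record
#'
#' @param rna_id identifier of the mature small RNA.
#' @param mature_seq mature sequence, 5' to 3', RNA or DNA alphabet.
#' @param kind `"miRNA"` or `"siRNA"`.
#' @param family_id optional seed-family identifier.
#' @return an object of class `small_rna`.
#' @export
small_rna <- function(rna_id, mature_seq, kind = c("miRNA", "siRNA"),
                      family_id = NA_character_) {
  kind <- match.arg(kind)
  check_alphabet(mature_seq, sprintf("small RNA '%s'", rna_id))
  if (nchar(mature_seq) < 8L) {
    stop(sprintf("small RNA '%s' is shorter than 8 nt", rna_id), call. = FALSE)
  }
  structure(list(rna_id = rna_id, mature_seq = normalize_seq(mature_seq),
                 kind = kind, family_id = as.character(family_id)),
            class = "small_rna")
}

#' @export
print.small_rna <- function(x, ...) {
  cat(sprintf("<small_rna> %s (%s) %s\n", x$rna_id, x$kind, x$mature_seq))
  invisible(x)
}

#' Construct a gene-annotation set
#'
#' Column-parallel container for per-gene 3' UTR sequences, per-base binary
#' conservation tracks, expression scores and optional promoter sequences
#' and housekeeping/developmental labels.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param utr_seq character vector of 3' UTR sequences (sense strand).
#' @param cons_track list of logical vectors, one per gene, same length as
#'   the corresponding UTR; `NULL` entries mean no conservation data.
#' @param expr_score non-negative numeric expression scores (RNA-Seq tag
#'   averages or similar).
#' @param promoter_seq optional character vector of promoter sequences.
#' @param is_housekeeping,is_developmental optional logical label vectors.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(gene_id, utr_seq, cons_track = NULL, expr_score = NULL,
                     promoter_seq = NULL, is_housekeeping = NULL,
                     is_developmental = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in gene_set: ",
         gene_id[duplicated(gene_id)][1], call. = FALSE)
  }
  if (length(utr_seq) != n) stop("utr_seq length mismatch", call. = FALSE)
  check_alphabet(utr_seq, "utr_seq")
  utr_seq <- normalize_seq(utr_seq)
  if (!is.null(cons_track)) {
    stopifnot(length(cons_track) == n)
    ok <- vapply(seq_len(n), function(i) {
      is.null(cons_track[[i]]) ||
        length(cons_track[[i]]) == nchar(utr_seq[i])
    }, logical(1))
    if (!all(ok)) {
      stop("cons_track length differs from UTR length for gene ",
           gene_id[which(!ok)[1]], call. = FALSE)
    }
  }
  if (!is.null(expr_score)) {
    stopifnot(length(expr_score) == n)
    if (any(expr_score < 0, na.rm = TRUE)) {
      stop("expr_score must be non-negative", call. = FALSE)
    }
  }
  structure(list(gene_id = as.character(gene_id), utr_seq = utr_seq,
                 cons_track = cons_track, expr_score = expr_score,
                 promoter_seq = if (is.null(promoter_seq)) NULL
                                else normalize_seq(promoter_seq),
                 is_housekeeping = is_housekeeping,
                 is_developmental = is_developmental),
            class = "gene_set")
}

#' @export
length.gene_set <- function(x) length(x$gene_id)

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d genes; UTR length %d-%d nt\n", length(x),
              min(nchar(x$utr_seq)), max(nchar(x$utr_seq))))
  invisible(x)
}

#' Construct one perturbation sample
#'
#' @param sample_id sample identifier.
#' @param small_rna the transfected/inhibited [small_rna()].
#' @param log_ratios named numeric vector, gene_id -> log-ratio. Scale is
#'   whatever the platform produced until [preprocess_log_ratios()] is run.
#' @param detection_pvalues optional named numeric vector in \[0,1\]; every
#'   name must also appear in `log_ratios`.
#' @return an object of class `mir_sample`.
#' @export
mir_sample <- function(sample_id, small_rna, log_ratios,
                       detection_pvalues = NULL) {
  stopifnot(inherits(small_rna, "small_rna"), !is.null(names(log_ratios)))
  if (!is.null(detection_pvalues)) {
    if (!all(names(detection_pvalues) %in% names(log_ratios))) {
      stop("detection_pvalues contains genes absent from log_ratios",
           call. = FALSE)
    }
    if (any(detection_pvalues < 0 | detection_pvalues > 1)) {
      stop("detection_pvalues outside [0,1]", call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, small_rna = small_rna,
                 log_ratios = log_ratios,
                 detection_pvalues = detection_pvalues),
            class = "mir_sample")
}

#' Construct an experiment set
#'
#' An experiment is a platform + assay combination holding one sample per
#' transfected (or inhibited) small RNA.
#'
#' @param experiment_id experiment identifier.
#' @param platform `"microarray"` or `"proteomics"`.
#' @param assay `"transfection"` or `"inhibition"`.
#' @param samples non-empty list of [mir_sample()] objects.
#' @param preprocessed internal flag: `TRUE` once log-ratios are on the
#'   internal log10 / negative-means-down convention.
#' @return an object of class `experiment_set`.
#' @export
experiment_set <- function(experiment_id,
                           platform = c("microarray", "proteomics"),
                           assay = c("transfection", "inhibition"),
                           samples, preprocessed = FALSE) {
  platform <- match.arg(platform)
  assay <- match.arg(assay)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "mir_sample")))
  structure(list(experiment_id = experiment_id, platform = platform,
                 assay = assay, samples = samples,
                 preprocessed = preprocessed),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %s: %s/%s, %d samples%s\n", x$experiment_id,
              x$platform, x$assay, length(x$samples),
              if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  invisible(x)
}

#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercased sequences (U kept as given;
#'   use [normalize_seq()] for matching).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  setNames(toupper(as.character(ss)), ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read a gene x sample log-ratio table into an experiment set
#'
#' The table is tab-delimited with a header row of sample ids and a first
#' column of gene ids; cells are numeric or `NA`. `NA` cells are treated as
#' unmeasured and omitted from the sample's log-ratio map. An optional
#' parallel p-value matrix (same layout) supplies per-gene detection
#' p-values (microarray platforms).
#'
#' @param path path to the log-ratio matrix.
#' @param platform,assay experiment platform and assay.
#' @param experiment_id experiment id; defaults to the file name.
#' @param rna_map named character vector sample_id -> rna_id, or `NULL` to
#'   use the sample id itself as the RNA id.
#' @param rnas optional named list of [small_rna()] objects keyed by rna_id;
#'   when absent, placeholder siRNA records are created.
#' @param pvalue_path optional path to the parallel detection p-value matrix.
#' @return an [experiment_set()].
#' @export
read_log_ratio_table <- function(path, platform, assay,
                                 experiment_id = NULL, rna_map = NULL,
                                 rnas = NULL, pvalue_path = NULL) {
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[^.]*$", "", basename(path))
  }
  mat <- read_numeric_matrix(path)
  pmat <- if (!is.null(pvalue_path)) read_numeric_matrix(pvalue_path) else NULL
  samples <- lapply(colnames(mat), function(sid) {
    v <- mat[, sid]
    v <- v[!is.na(v)]
    rid <- if (!is.null(rna_map)) unname(rna_map[[sid]]) else sid
    rna <- if (!is.null(rnas) && rid %in% names(rnas)) rnas[[rid]] else
      structure(list(rna_id = rid, mature_seq = NA_character_,
                     kind = "siRNA", family_id = NA_character_),
                class = "small_rna")
    pv <- NULL
    if (!is.null(pmat) && sid %in% colnames(pmat)) {
      pv <- pmat[, sid]
      pv <- pv[!is.na(pv)]
      pv <- pv[names(pv) %in% names(v)]
    }
    mir_sample(sid, rna, v, pv)
  })
  experiment_set(experiment_id, platform, assay, samples)
}

# Tab-delimited numeric matrix, rows = genes, columns = samples. Errors
# name the offending cell.
read_numeric_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   colClasses = "character", check.names = FALSE,
                   comment.char = "#")
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    cell <- df[[j]]
    is_na <- is.na(cell) | cell == "NA" | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_na & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   cell[i], rownames(df)[i], colnames(df)[j], path),
           call. = FALSE)
    }
    m[, j] <- ifelse(is_na, NA_real_, num)
  }
  m
}

#' Write an experiment set's log-ratios as a gene x sample matrix
#'
#' @param exp an [experiment_set()].
#' @param path output path.
#' @param digits significant digits (default keeps full double precision).
#' @return `path`, invisibly.
#' @export
write_log_ratio_table <- function(exp, path, digits = 17) {
  genes <- sort(unique(unlist(lapply(exp$samples,
                                     function(s) names(s$log_ratios)))))
  m <- sapply(exp$samples, function(s) {
    unname(s$log_ratios[genes])
  })
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes,
                              vapply(exp$samples, `[[`, "", "sample_id")))
  df <- data.frame(gene_id = genes, signif(m, digits), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Put an experiment's log-ratios on the internal analysis scale
#'
#' Internal convention: log10 scale, negative values = candidate
#' down-regulation in every assay. Log2 input is rescaled by `log10(2)`;
#' inhibition experiments are negated, because de-repressed (up-regulated)
#' genes are the targeting candidates there.
#'
#' Calling this with `input_log_base = 10` on a transfection set is a no-op,
#' so preprocessing is idempotent on already-internal data.
#'
#' @param exp an [experiment_set()].
#' @param input_log_base 2 or 10; the log base of the stored values.
#' @return the experiment set with rescaled (and possibly negated)
#'   log-ratios and `preprocessed = TRUE`.
#' @export
preprocess_log_ratios <- function(exp, input_log_base = 10) {
  stopifnot(inherits(exp, "experiment_set"))
  if (!input_log_base %in% c(2, 10)) {
    stop("input_log_base must be 2 or 10", call. = FALSE)
  }
  scale <- if (input_log_base == 2) log10(2) else 1
  sign <- if (exp$assay == "inhibition") -1 else 1
  exp$samples <- lapply(exp$samples, function(s) {
    s$log_ratios <- sign * scale * s$log_ratios
    s
  })
  exp$preprocessed <- TRUE
  exp
}

#' Read per-gene mapped-read positions (BED5)
#'
#' BED5 lines `chrom start end name score` where `chrom` is a gene id,
#' intervals are 0-based half-open on the 3' UTR, and `score` is the mapped
#' read count at that position.
#'
#' @param path path to the BED file.
#' @return named list, gene_id -> data.frame(position, read_count).
#' @export
read_read_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5)) {
    stop("BED5 line with fewer than 5 fields in ", path, call. = FALSE)
  }
  gene <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  count <- as.numeric(vapply(parts, `[[`, "", 5L))
  if (any(is.na(pos)) || any(pos < 0)) {
    stop("invalid start position in ", path, call. = FALSE)
  }
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count))) {
    stop("read counts must be non-negative integers in ", path, call. = FALSE)
  }
  df <- data.frame(gene_id = gene, position = pos,
                   read_count = as.integer(count))
  split(df[c("position", "read_count")], df$gene_id)
}

#' Read a two-column score table
#'
#' Tab-delimited `id <tab> score` with a header row; used for expression
#' scores and endogenous family expression rankings.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "numeric"))
  setNames(df[[2]], df[[1]])
}

#' Read a per-gene binary conservation track table
#'
#' Tab-delimited `gene_id <tab> track` where track is a string of 0/1 flags,
#' one per UTR base.
#'
#' @param path file path.
#' @return named list of logical vectors.
#' @export
read_conservation_tracks <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  tracks <- lapply(df[[2]], function(s) {
    strsplit(s, "", fixed = TRUE)[[1]] == "1"
  })
  names(tracks) <- df[[1]]
  tracks
}
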