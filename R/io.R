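#' Read a PLINK bed/bim/fam triple
#'
#' Parses the binary SNP-major PLINK 1 format (magic bytes 0x6c 0x1b,
#' mode 0x01) into an additive dosage matrix counting the A1 allele, with
#' missing calls as `NA`.  With `reorient = TRUE` (default) columns whose
#' A1 frequency exceeds 0.5 are flipped (dosage 0 <-> 2, alleles swapped)
#' so that dosages always count the minor allele.
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @param reorient flip columns to minor-allele dosage coding.
#' @return list with `genotype` (n x m integer matrix, subjects in fam
#'   order, SNP ids from the bim), `snps` (bim table, with a `flipped`
#'   column) and `samples` (fam table).
#' @export
readPlink <- function(prefix, reorient = TRUE) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  snps <- utils::read.table(bim, col.names = c("chr", "id", "cm", "pos",
                                               "a1", "a2"),
                            colClasses = c("character", "character",
                                           "numeric", "integer",
                                           "character", "character"))
  samples <- utils::read.table(fam, col.names = c("fid", "iid", "pid",
                                                  "mid", "sex", "pheno"))
  n <- nrow(samples)
  m <- nrow(snps)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (magic byte mismatch)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)
  if (length(raw) != 3L + bps * m)
    stop(sprintf("bed dimension mismatch: expected %d data bytes, found %d",
                 bps * m, length(raw) - 3L))
  body <- raw[-(1:3)]
  # unpack 2-bit codes, subject 1 in the lowest bits of each byte
  ints <- as.integer(body)
  codes <- matrix(0L, nrow = bps * 4L, ncol = m)
  shift <- c(1L, 4L, 16L, 64L)
  for (s in 1:4)
    codes[seq(s, bps * 4L, by = 4L), ] <- (matrix(ints, bps, m) %/%
                                             shift[s]) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  geno <- matrix(NA_integer_, n, m, dimnames = list(samples$iid, snps$id))
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  snps$flipped <- FALSE
  if (reorient) {
    p <- colMeans(geno, na.rm = TRUE) / 2
    flip <- !is.na(p) & p > 0.5
    if (any(flip)) {
      geno[, flip] <- 2L - geno[, flip]
      tmp <- snps$a1[flip]
      snps$a1[flip] <- snps$a2[flip]
      snps$a2[flip] <- tmp
      snps$flipped <- flip
    }
  }
  list(genotype = geno, snps = snps, samples = samples)
}

#' Write a PLINK bed/bim/fam triple
#'
#' Inverse of [readPlink()]: encodes an additive dosage matrix (dosage of
#' A1, `NA` = missing) as a SNP-major PLINK 1 bed file with companion
#' bim/fam text files.
#'
#' @param prefix output path prefix.
#' @param genotype n x m dosage matrix, subjects in rows.
#' @param snps optional bim table (columns chr, id, cm, pos, a1, a2);
#'   defaults are synthesized from the column names.
#' @param samples optional fam table.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(prefix, genotype, snps = NULL, samples = NULL) {
  genotype <- as.matrix(genotype)
  n <- nrow(genotype)
  m <- ncol(genotype)
  ids <- colnames(genotype)
  if (is.null(ids)) ids <- paste0("SNP", seq_len(m))
  if (is.null(snps))
    snps <- data.frame(chr = 1L, id = ids, cm = 0, pos = seq_len(m),
                       a1 = "A", a2 = "B")
  if (is.null(samples))
    samples <- data.frame(fid = seq_len(n), iid = seq_len(n), pid = 0L,
                          mid = 0L, sex = 0L, pheno = -9L)
  utils::write.table(snps, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(samples, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bps <- ceiling(n / 4)
  code <- matrix(1L, bps * 4L, m)   # pad positions encode "missing"
  cd <- matrix(1L, n, m)
  cd[genotype == 2L] <- 0L
  cd[genotype == 1L] <- 2L
  cd[genotype == 0L] <- 3L
  code[seq_len(n), ] <- cd
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bps, m)
  for (s in 1:4)
    bytes <- bytes + code[seq(s, bps * 4L, by = 4L), , drop = FALSE] * shift[s]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Plain-text genotype table I/O
#'
#' Tab-separated internal genotype format for small fixtures: a `sample`
#' column followed by one 0/1/2 column per SNP (`NA` = missing).
#'
#' @param path file path.
#' @param genotype dosage matrix, subjects in rows (for writing).
#' @return for reading, an n x m integer matrix with SNP column names.
#' @export
readGenoTSV <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- tab[[1]]
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  g
}

#' @rdname readGenoTSV
#' @export
writeGenoTSV <- function(path, genotype) {
  genotype <- as.matrix(genotype)
  if (is.null(colnames(genotype)))
    colnames(genotype) <- paste0("SNP", seq_len(ncol(genotype)))
  sample <- rownames(genotype)
  if (is.null(sample)) sample <- seq_len(nrow(genotype))
  utils::write.table(cbind(data.frame(sample = sample),
                           as.data.frame(genotype)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table into survival outcome form
#'
#' Delimited text with named columns mapped onto (time, status,
#' covariates).  Under the age-of-onset coding the status column holds the
#' case indicator (a case contributes an event at diagnosis age; a control
#' is censored at interview age) and the time column holds that age.
#' Rows with a negative time, a status outside {0, 1} or a missing mapped
#' value are dropped and reported.
#'
#' @param path file path (tab- or comma-separated, autodetected from the
#'   extension).
#' @param time,status names of the time and status columns.
#' @param covariates character vector of covariate column names.
#' @return data.frame with columns `time`, `status` and the covariates;
#'   the number of dropped rows is attached as attribute `"dropped"`.
#' @export
readPheno <- function(path, time = "time", status = "status",
                      covariates = character()) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c(time, status, covariates)
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(time = as.numeric(tab[[time]]),
                    status = as.integer(tab[[status]]))
  for (cv in covariates) out[[cv]] <- tab[[cv]]
  ok <- !is.na(out$time) & out$time >= 0 &
    !is.na(out$status) & out$status %in% c(0L, 1L)
  if (length(covariates))
    ok <- ok & stats::complete.cases(out[, covariates, drop = FALSE])
  if (any(!ok))
    message(sum(!ok), " row(s) dropped (negative time, invalid status or ",
            "missing covariate)")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Assemble a GenoSurvExperiment from PLINK + phenotype files
#'
#' @param prefix PLINK file prefix (see [readPlink()]).
#' @param phenoPath phenotype table (see [readPheno()]); subjects are
#'   matched by row order and must agree in count.
#' @param ... passed to [readPheno()].
#' @return a [GenoSurvExperiment-class].
#' @export
readGenoSurv <- function(prefix, phenoPath, ...) {
  pl <- readPlink(prefix)
  ph <- readPheno(phenoPath, ...)
  if (nrow(ph) != nrow(pl$genotype))
    stop("phenotype rows (after filtering) and fam subjects differ; ",
         "align the inputs first")
  covs <- ph[, setdiff(colnames(ph), c("time", "status")), drop = FALSE]
  GenoSurvExperiment(pl$genotype, time = ph$time, status = ph$status,
                     covariates = if (ncol(covs)) covs else NULL,
                     snpInfo = pl$snps)
}

#' Write a structured run log
#'
#' Records, as JSON, everything needed to reproduce a run: the
#' configuration (including every seed), package version, timestamp and
#' any result summaries (e.g. row counts surviving each filter).
#'
#' @param path output path.
#' @param config named list of parameters; every stochastic step's seed
#'   belongs here.
#' @param results optional named list of result summaries.
#' @return the log (a list), invisibly.
#' @export
writeRunLog <- function(path, config, results = list()) {
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package = "esmdr",
              version = as.character(utils::packageVersion("esmdr")),
              config = config, results = results)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(log)
}
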