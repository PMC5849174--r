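#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a SNP manifest
#'
#' A SNP manifest describes the panel: one row per SNP with its identity,
#' genomic location, the effect (risk) allele whose count enters dosages and
#' scores, the other allele, and an optional external weight on the log
#' odds-ratio scale. Effect-allele orientation is always taken from the
#' manifest, never inferred from allele frequency: the risk allele of a
#' candidate SNP is defined by the source literature, not by the data at hand.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (character).
#' @param pos 1-based positions (non-negative integers).
#' @param effect_allele,other_allele single bases in A/C/G/T; must differ
#'   within each row.
#' @param external_weight optional numeric per-SNP weight (natural-log OR).
#' @return A `data.frame` of class `snp_manifest`.
#' @export
snp_manifest <- function(snp_id, chrom, pos, effect_allele, other_allele,
                         external_weight = NA_real_) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in manifest: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  if (!all(effect_allele %in% VALID_ALLELES) ||
      !all(other_allele %in% VALID_ALLELES)) {
    stop("alleles must be one of A/C/G/T")
  }
  if (any(effect_allele == other_allele)) {
    bad <- snp_id[effect_allele == other_allele]
    stop("effect_allele equals other_allele for: ", paste(bad, collapse = ", "))
  }
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0)) stop("pos must be non-negative integers")
  out <- data.frame(
    snp_id = snp_id, chrom = as.character(chrom), pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    external_weight = as.numeric(external_weight),
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_manifest", "data.frame")
  out
}

#' Construct a genotype matrix
#'
#' Samples by SNPs effect-allele dosages in \{0, 1, 2\} with `NA` for missing
#' calls, tied to a [snp_manifest()] that fixes the effect-allele orientation.
#'
#' @param dosage numeric or integer matrix, samples in rows, SNPs in columns;
#'   entries 0/1/2 or `NA`.
#' @param sample_ids unique sample identifiers, one per row.
#' @param snps a [snp_manifest()] with one row per dosage column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(dosage) != length(sample_ids)) {
    stop("dosage has ", nrow(dosage), " rows but ", length(sample_ids),
         " sample ids")
  }
  if (!inherits(snps, "snp_manifest")) stop("snps must be a snp_manifest")
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage has ", ncol(dosage), " columns but manifest has ",
         nrow(snps), " SNPs")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("non-missing dosages must be 0, 1 or 2")
  }
  dimnames(dosage) <- list(sample_ids, snps$snp_id)
  structure(list(sample_ids = sample_ids, snps = snps, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              length(x$sample_ids), nrow(x$snps), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or logical/integer index; `NULL` keeps all.
#' @param snps SNP ids or logical/integer index; `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else {
    if (is.character(samples)) {
      idx <- match(samples, gm$sample_ids)
      if (anyNA(idx)) stop("unknown sample id: ",
                           paste(samples[is.na(idx)], collapse = ", "))
      idx
    } else samples
  }
  ji <- if (is.null(snps)) seq_len(nrow(gm$snps)) else {
    if (is.character(snps)) {
      idx <- match(snps, gm$snps$snp_id)
      if (anyNA(idx)) stop("unknown snp id: ",
                           paste(snps[is.na(idx)], collapse = ", "))
      idx
    } else snps
  }
  man <- gm$snps[ji, , drop = FALSE]
  class(man) <- c("snp_manifest", "data.frame")
  genotype_matrix(gm$dosage[si, ji, drop = FALSE], gm$sample_ids[si], man)
}

#' Construct a phenotype table
#'
#' @param sample_id character sample identifiers (unique).
#' @param status `"case"`/`"control"` per sample; never missing.
#' @param age age in years; `NA` allowed (such samples are usable for
#'   unadjusted analyses only).
#' @return A `data.frame` of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_id, status, age = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id in phenotypes: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  status <- as.character(status)
  if (!all(status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control' with no missing values")
  }
  age <- as.numeric(age)
  if (any(!is.na(age) & age <= 0)) stop("age must be positive")
  out <- data.frame(sample_id = sample_id, status = status, age = age,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

parse_status <- function(x, dialect = c("case_control", "zero_one", "plink")) {
  dialect <- match.arg(dialect)
  x <- tolower(trimws(as.character(x)))
  out <- switch(dialect,
    case_control = ifelse(x == "case", "case",
                   ifelse(x == "control", "control", NA_character_)),
    zero_one = ifelse(x == "1", "case", ifelse(x == "0", "control",
                                               NA_character_)),
    plink = ifelse(x == "2", "case", ifelse(x == "1", "control",
                                            NA_character_))
  )
  if (anyNA(out)) {
    stop("unparseable status value(s) under dialect '", dialect, "': ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a phenotype table from TSV
#'
#' Expects columns `sample_id`, `status`, `age`. The status encoding is
#' declared explicitly rather than guessed: `case_control` (literal words,
#' case-insensitive), `zero_one` (control = 0, case = 1) or `plink`
#' (control = 1, case = 2).
#'
#' @param path TSV file path.
#' @param status_dialect one of `"case_control"`, `"zero_one"`, `"plink"`.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path,
                            status_dialect = c("case_control", "zero_one",
                                               "plink")) {
  status_dialect <- match.arg(status_dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "status", "age")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns sample_id, status, age; got: ",
         paste(names(df), collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(df$age))
  phenotype_table(df$sample_id, parse_status(df$status, status_dialect), age)
}

#' Write a phenotype table as TSV
#' @param phen a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(as.data.frame(phen), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP manifest from TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele` and
#' optionally `external_weight`.
#' @param path TSV file path.
#' @return A [snp_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  w <- if ("external_weight" %in% names(df)) df$external_weight else NA_real_
  snp_manifest(df$snp_id, df$chrom, df$pos, df$effect_allele,
               df$other_allele, w)
}

#' Write a SNP manifest as TSV
#' @param man a [snp_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(man, path) {
  utils::write.table(as.data.frame(man), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from PLINK-text or TSV
#'
#' Both dialects are oriented against the manifest: dosages count copies of
#' the manifest's effect allele. For `plink_text`, `path` is the file prefix
#' (`<path>.ped` and `<path>.map` must exist) and allele pairs are converted
#' to effect-allele counts; an allele not matching the manifest's
#' effect/other pair is an orientation error naming the SNP. For `tsv`,
#' the file has a `sample_id` column followed by one column per SNP id with
#' entries 0/1/2/NA.
#'
#' @param path file path (TSV) or PLINK prefix.
#' @param manifest a [snp_manifest()] covering every SNP in the file.
#' @param dialect `"tsv"` or `"plink_text"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, manifest,
                           dialect = c("tsv", "plink_text")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_genotypes_tsv(path, manifest)
  else read_genotypes_plink(path, manifest)
}

read_genotypes_tsv <- function(path, manifest) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("TSV genotype file must start with a sample_id column")
  }
  snp_ids <- names(df)[-1]
  miss <- setdiff(snp_ids, manifest$snp_id)
  if (length(miss)) stop("SNPs absent from manifest: ",
                         paste(miss, collapse = ", "))
  man <- manifest[match(snp_ids, manifest$snp_id), , drop = FALSE]
  class(man) <- c("snp_manifest", "data.frame")
  if (nrow(df) == 0) {
    return(genotype_matrix(matrix(integer(), 0, length(snp_ids)),
                           character(), man))
  }
  dose <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(dose) <- "integer")
  bad <- which(!is.na(dose) & !(dose %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("parse error at data line ", bad[1, 1], ", SNP ", snp_ids[bad[1, 2]],
         ": dosage must be 0/1/2/NA")
  }
  genotype_matrix(dose, df$sample_id, man)
}

read_genotypes_plink <- function(prefix, manifest) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path)) {
    stop("expected ", ped_path, " and ", map_path)
  }
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  idx <- match(map$snp_id, manifest$snp_id)
  if (anyNA(idx)) {
    stop("SNPs in .map absent from manifest: ",
         paste(map$snp_id[is.na(idx)], collapse = ", "))
  }
  man <- manifest[idx, , drop = FALSE]
  class(man) <- c("snp_manifest", "data.frame")
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  dose <- matrix(NA_integer_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop("parse error in ", ped_path, " line ", i, ": expected ",
           6 + 2 * m, " fields, got ", length(f))
    }
    ids[i] <- f[2]
    a1 <- toupper(f[seq(7, by = 2, length.out = m)])
    a2 <- toupper(f[seq(8, by = 2, length.out = m)])
    missing <- a1 == "0" & a2 == "0"
    for (j in which(!missing)) {
      ok <- c(man$effect_allele[j], man$other_allele[j])
      if (!(a1[j] %in% ok) || !(a2[j] %in% ok)) {
        stop("orientation error at SNP ", man$snp_id[j], " (line ", i,
             "): allele pair ", a1[j], "/", a2[j],
             " not in {", ok[1], ",", ok[2], "}")
      }
      dose[i, j] <- (a1[j] == man$effect_allele[j]) +
                    (a2[j] == man$effect_allele[j])
    }
  }
  genotype_matrix(dose, ids, man)
}

#' Write genotypes in PLINK-text or TSV
#'
#' Lossless for dosage and missingness in both dialects; missing calls are
#' written as `NA` (TSV) or `0 0` (ped).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (TSV) or PLINK prefix.
#' @param dialect `"tsv"` or `"plink_text"`.
#' @param phen optional [phenotype_table()]; used to fill the ped phenotype
#'   column (2 = case, 1 = control, 0 = unknown).
#' @return The path, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("tsv", "plink_text"),
                            phen = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (dialect == "tsv") {
    df <- data.frame(sample_id = gm$sample_ids, stringsAsFactors = FALSE)
    dose <- gm$dosage
    for (j in seq_len(ncol(dose))) df[[gm$snps$snp_id[j]]] <- dose[, j]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  man <- gm$snps
  map <- data.frame(chrom = man$chrom, snp_id = man$snp_id, cm = 0,
                    pos = man$pos)
  utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pheno_code <- rep(0L, length(gm$sample_ids))
  if (!is.null(phen)) {
    st <- phen$status[match(gm$sample_ids, phen$sample_id)]
    pheno_code <- ifelse(is.na(st), 0L, ifelse(st == "case", 2L, 1L))
  }
  m <- nrow(man)
  con <- file(paste0(path, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_along(gm$sample_ids)) {
    g <- gm$dosage[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, man$effect_allele,
                                       man$other_allele))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, man$effect_allele,
                                       man$other_allele))
    geno <- character(2 * m)
    geno[seq(1, by = 2, length.out = m)] <- a1
    geno[seq(2, by = 2, length.out = m)] <- a2
    writeLines(paste(c(gm$sample_ids[i], gm$sample_ids[i], "0", "0", "0",
                       pheno_code[i], geno), collapse = " "), con)
  }
  invisible(path)
}

#' Join genotypes and phenotypes by sample id
#'
#' The join is by id, never by row order; the genotype matrix is reordered to
#' the intersection and a reconciliation log reports every sample present on
#' only one side.
#'
#' @param gm a [genotype_matrix()].
#' @param phen a [phenotype_table()].
#' @return A list with elements `gm`, `phen` (aligned, same sample order) and
#'   `log` (counts and ids of unmatched samples).
#' @export
join_cohort <- function(gm, phen) {
  common <- intersect(gm$sample_ids, phen$sample_id)
  only_geno <- setdiff(gm$sample_ids, common)
  only_phen <- setdiff(phen$sample_id, common)
  gm2 <- subset_genotypes(gm, samples = common)
  phen2 <- phen[match(common, phen$sample_id), , drop = FALSE]
  rownames(phen2) <- NULL
  class(phen2) <- c("phenotype_table", "data.frame")
  list(gm = gm2, phen = phen2,
       log = list(n_joined = length(common),
                  n_cases = sum(phen2$status == "case"),
                  n_controls = sum(phen2$status == "control"),
                  genotype_only = only_geno, phenotype_only = only_phen))
}
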