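#' Genotype matrix container
#'
#' Wraps an n x p matrix of additive allele counts (0/1/2, `NA` for missing)
#' together with SNP identifiers and an optional map (chromosome, base-pair
#' position per SNP).
#'
#' @param values numeric matrix, individuals in rows, SNPs in columns; entries
#'   in \{0, 1, 2\} or `NA`.
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   column names).
#' @param map optional data.frame with columns `snp_id`, `chromosome`,
#'   `position` (1-based).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values), map = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(values)) stop("length of 'snp_ids' must match column count")
  if (anyDuplicated(snp_ids)) stop("SNP identifiers must be unique")
  bad <- values[!is.na(values)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("genotype values must be additive allele counts in {0, 1, 2} or NA")
  }
  colnames(values) <- snp_ids
  if (!is.null(map)) {
    map <- as.data.frame(map)
    need <- c("snp_id", "chromosome", "position")
    if (!all(need %in% names(map))) stop("'map' needs columns snp_id, chromosome, position")
    map <- map[match(snp_ids, map$snp_id), need]
    if (anyNA(map$snp_id)) stop("map is missing entries for some SNPs")
    rownames(map) <- NULL
  }
  structure(list(values = values, snp_ids = snp_ids, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s map)\n",
              nrow(x$values), ncol(x$values), if (is.null(x$map)) "no" else "with"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Trait matrix container
#'
#' @param values numeric matrix, individuals in rows, traits in columns.
#' @param trait_names trait labels (defaults to column names).
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, trait_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1) stop("at least one trait is required")
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  if (length(trait_names) != ncol(values)) stop("length of 'trait_names' must match column count")
  colnames(values) <- as.character(trait_names)
  structure(list(values = values, trait_names = colnames(values)),
            class = "trait_matrix")
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Covariate matrix container
#'
#' @param values numeric matrix (e.g. sex, age, body mass index); an intercept
#'   is always added internally when adjusting, do not include one.
#' @param names covariate labels.
#' @return object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(names)) names <- paste0("cov", seq_len(ncol(values)))
  colnames(values) <- as.character(names)
  structure(list(values = values, names = colnames(values)),
            class = "covariate_matrix")
}

as_values <- function(x) {
  if (inherits(x, c("genotype_matrix", "trait_matrix", "covariate_matrix"))) x$values
  else as.matrix(x)
}

#' Read a genotype file
#'
#' Two dialects are supported: a plain delimited matrix (first row SNP ids,
#' one row per individual, `NA` for missing) and the PLINK RAW additive dosage
#' dialect (header `FID IID PAT MAT SEX PHENOTYPE` followed by `SNP_allele`
#' columns).
#'
#' @param file path to the genotype file.
#' @param format `"auto"` (detect from header), `"matrix"` or `"plink-raw"`.
#' @param map_file optional tab-delimited map with 3 columns
#'   (snp_id, chromosome, position), no header.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(file, format = c("auto", "matrix", "plink-raw"),
                           map_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("genotype file not found: ", file)
  header <- strsplit(readLines(file, n = 1L), "[ \t]+")[[1]]
  if (format == "auto") {
    plink_lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    format <- if (length(header) >= 6 && identical(toupper(header[1:6]), plink_lead))
      "plink-raw" else "matrix"
  }
  tab <- utils::read.table(file, header = TRUE, check.names = FALSE,
                           na.strings = c("NA", "-9"))
  if (format == "plink-raw") {
    geno <- as.matrix(tab[, -(1:6), drop = FALSE])
    # strip the counted-allele suffix, e.g. rs123_A -> rs123
    ids <- sub("_[ACGT0-9]+$", "", colnames(geno))
  } else {
    geno <- as.matrix(tab)
    ids <- colnames(geno)
  }
  map <- NULL
  if (!is.null(map_file)) map <- read_snp_map(map_file)
  genotype_matrix(geno, snp_ids = ids, map = map)
}

#' Read a SNP map file
#'
#' @param file tab-delimited, 3 columns (snp_id, chromosome, position),
#'   no header, 1-based positions.
#' @return data.frame with columns `snp_id`, `chromosome`, `position`.
#' @export
read_snp_map <- function(file) {
  if (!file.exists(file)) stop("map file not found: ", file)
  map <- utils::read.table(file, header = FALSE, sep = "\t",
                           col.names = c("snp_id", "chromosome", "position"),
                           colClasses = c("character", "character", "integer"))
  map
}

#' Read a phenotype or covariate table
#'
#' Tab- or whitespace-delimited with a header row, one row per individual in
#' the same order as the genotype file. An optional identifier column can be
#' named for a consistency check against a reference id vector.
#'
#' @param file path.
#' @param id_col optional name of an identifier column (removed from the
#'   numeric payload).
#' @param ids optional reference identifiers to check `id_col` against.
#' @return numeric matrix with column names.
#' @export
read_trait_table <- function(file, id_col = NULL, ids = NULL) {
  if (!file.exists(file)) stop("phenotype/covariate file not found: ", file)
  tab <- utils::read.table(file, header = TRUE, check.names = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(tab)) stop("id column '", id_col, "' not present in ", file)
    file_ids <- as.character(tab[[id_col]])
    tab[[id_col]] <- NULL
    if (!is.null(ids) && !identical(file_ids, as.character(ids))) {
      stop("row order of ", file, " does not match the genotype individuals")
    }
  }
  as.matrix(tab)
}

#' Write a genotype matrix in the plain delimited dialect
#' @param G a [genotype_matrix()].
#' @param file output path.
#' @export
write_genotypes <- function(G, file) {
  utils::write.table(as_values(G), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' QC configuration
#'
#' @param maf_min minor allele frequency below which a SNP is excluded
#'   (strict `<`; default 0.01).
#' @param hwe_p_min Hardy-Weinberg equilibrium test p-value below which a SNP
#'   is excluded (strict `<`; default 1e-4).
#' @param tag_r2 squared-correlation threshold for tagging (default 0.80).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, hwe_p_min = 1e-4, tag_r2 = 0.80) {
  stopifnot(maf_min > 0, maf_min < 0.5, hwe_p_min > 0, hwe_p_min < 1,
            tag_r2 > 0, tag_r2 <= 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min, tag_r2 = tag_r2),
            class = "qc_config")
}

# 1-df chi-square Hardy-Weinberg test from genotype counts (n0, n1, n2).
# Expected counts under HWE from the estimated allele frequency; no
# continuity correction. Returns the p-value.
hwe_test <- function(n0, n1, n2) {
  m <- n0 + n1 + n2
  if (m == 0) return(NA_real_)
  f <- (n1 + 2 * n2) / (2 * m)          # frequency of the counted allele
  e <- m * c((1 - f)^2, 2 * f * (1 - f), f^2)
  o <- c(n0, n1, n2)
  keep <- e > 0
  if (!any(keep)) return(1)
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Quality-control filter on SNPs
#'
#' Retains SNPs with minor allele frequency at least `maf_min`, a
#' Hardy-Weinberg equilibrium 1-df chi-square test p-value of at least
#' `hwe_p_min`, and at least two observed genotype values (non-monomorphic).
#' Both exclusions are strict inequalities, matching the usual reporting
#' convention "MAF < 0.01 or HWE p < 1e-4 excluded". Missing genotypes are
#' ignored in the per-SNP counts. Column order is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return list of class `qc_result`: `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (data.frame with `snp_id`, `maf`,
#'   `hwe_p`, `kept`, `reason`).
#' @export
qc_filter <- function(G, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  X <- as_values(G)
  p <- ncol(X)
  maf <- hwe_p <- numeric(p)
  mono <- logical(p)
  for (j in seq_len(p)) {
    x <- X[, j]
    x <- x[!is.na(x)]
    n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
    f <- if (length(x)) (n1 + 2 * n2) / (2 * length(x)) else NA_real_
    maf[j] <- min(f, 1 - f)
    hwe_p[j] <- hwe_test(n0, n1, n2)
    mono[j] <- length(unique(x)) < 2
  }
  kept <- !mono & maf >= cfg$maf_min & hwe_p >= cfg$hwe_p_min
  kept[is.na(kept)] <- FALSE
  reason <- rep("", p)
  reason[maf < cfg$maf_min | is.na(maf)] <- "low MAF"
  reason[!is.na(hwe_p) & hwe_p < cfg$hwe_p_min] <- "HWE deviation"
  reason[mono] <- "monomorphic"
  report <- data.frame(snp_id = if (inherits(G, "genotype_matrix")) G$snp_ids
                       else colnames(X),
                       maf = maf, hwe_p = hwe_p, kept = kept,
                       reason = ifelse(kept, "", reason),
                       stringsAsFactors = FALSE)
  if (!any(kept)) stop("empty panel: all SNPs removed by QC")
  Gk <- if (inherits(G, "genotype_matrix")) {
    genotype_matrix(X[, kept, drop = FALSE], snp_ids = G$snp_ids[kept],
                    map = if (is.null(G$map)) NULL else G$map[kept, , drop = FALSE])
  } else {
    genotype_matrix(X[, kept, drop = FALSE])
  }
  structure(list(genotypes = Gk, report = report), class = "qc_result")
}

#' Mean-impute missing genotypes
#'
#' Missing entries of each SNP are replaced by the SNP's mean observed allele
#' count. A warning reports the imputed fraction. Intended as a pragmatic
#' fallback; model-based imputation is outside the scope of this package.
#'
#' @param G a [genotype_matrix()] or plain matrix.
#' @return numeric matrix with no missing values.
#' @export
impute_mean <- function(G) {
  X <- as_values(G)
  miss <- is.na(X)
  if (any(miss)) {
    warning(sprintf("mean-imputing %.2f%% missing genotype entries",
                    100 * mean(miss)))
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}

#' Greedy r-squared tagging
#'
#' Reduces the SNP panel by selecting tag SNPs such that every removed SNP has
#' pairwise squared Pearson correlation strictly above `r2` with its assigned
#' tag. Tags are chosen greedily: the SNP covering the largest number of
#' yet-uncovered SNPs is selected at each step (ties broken by lower column
#' index), in the style of Carlson et al. tag selection. Correlations are
#' computed on mean-imputed additive codes.
#'
#' @param G a [genotype_matrix()] (QC already applied).
#' @param r2 squared-correlation threshold (default 0.80).
#' @return list of class `tag_result`: `tags` (a [genotype_matrix()] of
#'   retained SNPs) and `assignment` (named character vector mapping every
#'   input SNP id to its tag's id; tags map to themselves).
#' @export
greedy_tag <- function(G, r2 = 0.80) {
  X <- suppressWarnings(impute_mean(G))
  ids <- if (inherits(G, "genotype_matrix")) G$snp_ids else colnames(X)
  p <- ncol(X)
  if (p <= 1) {
    return(structure(list(tags = G, assignment = stats::setNames(ids, ids)),
                     class = "tag_result"))
  }
  r2mat <- suppressWarnings(stats::cor(X))^2
  r2mat[is.na(r2mat)] <- 0
  covers <- r2mat > r2
  diag(covers) <- TRUE
  uncovered <- rep(TRUE, p)
  assignment <- stats::setNames(rep(NA_character_, p), ids)
  tags <- integer(0)
  while (any(uncovered)) {
    gain <- colSums(covers & uncovered)
    pick <- which.max(gain)  # which.max takes the lowest index on ties
    tags <- c(tags, pick)
    newly <- which(covers[, pick] & uncovered)
    assignment[newly] <- ids[pick]
    assignment[pick] <- ids[pick]  # a tag always represents itself
    uncovered[newly] <- FALSE
    uncovered[pick] <- FALSE
  }
  tags <- sort(tags)
  Gt <- if (inherits(G, "genotype_matrix")) {
    genotype_matrix(G$values[, tags, drop = FALSE], snp_ids = ids[tags],
                    map = if (is.null(G$map)) NULL else G$map[tags, , drop = FALSE])
  } else {
    genotype_matrix(X[, tags, drop = FALSE], snp_ids = ids[tags])
  }
  structure(list(tags = Gt, assignment = assignment), class = "tag_result")
}

#' Inverse-normal (normal quantile) transformation
#'
#' Maps a trait to normal scores via `qnorm((rank - 3/8) / (n + 1/4))`
#' (Blom-type offset), with average ranks for ties. Strictly monotone in the
#' input ranks.
#'
#' @param y numeric vector, `n >= 2`, no missing values.
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(y) {
  if (anyNA(y)) stop("missing values must be handled before transformation")
  n <- length(y)
  if (n < 2) stop("need at least two observations")
  if (length(unique(y)) < 2) stop("transform undefined for a constant trait")
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Remove covariate effects by projection
#'
#' Projects traits and genotypes onto the orthogonal complement of the column
#' span of `[1, C]` (intercept plus covariates). For the conjugate model this
#' is mathematically equivalent to carrying the covariates as always-included
#' regressors; the count of projected-out columns `c_eff = 1 + c` must be
#' propagated to the marginal likelihood's degrees of freedom.
#'
#' @param Y a [trait_matrix()] or matrix.
#' @param G a [genotype_matrix()] or matrix (missing entries are
#'   mean-imputed first).
#' @param C a [covariate_matrix()], matrix, or `NULL` (intercept only).
#' @return list with `Y` (projected traits), `X` (projected genotypes),
#'   `c_eff`, and `snp_ids`.
#' @export
adjust_for_covariates <- function(Y, G, C = NULL) {
  Ym <- as_values(Y)
  Xm <- impute_mean(G)
  if (nrow(Ym) != nrow(Xm)) stop("trait and genotype row counts differ")
  n <- nrow(Ym)
  Z <- cbind(`(intercept)` = rep(1, n), if (!is.null(C)) as_values(C))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(Y = qr.resid(qz, Ym), X = qr.resid(qz, Xm), c_eff = ncol(Z),
       snp_ids = if (inherits(G, "genotype_matrix")) G$snp_ids else colnames(Xm))
}
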