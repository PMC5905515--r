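#' Numeric genotype coding under a genetic model
#'
#' With A the major and a the minor allele: additive codes AA/Aa/aa as 2/1/0,
#' recessive as 1/0/0 and dominant as 1/1/0. Genotypes are unordered allele
#' pairs, given as two-character strings (`"TC"`) or slash-separated
#' (`"T/C"`); missing genotypes (NA or empty) propagate as NA.
#'
#' @param genotype character vector of allele pairs.
#' @param model one of `"additive"`, `"recessive"`, `"dominant"`.
#' @param major_allele the allele treated as A.
#' @param minor_allele optional; when given, any other allele errors.
#' @return numeric vector of codes.
#' @export
encode_genotype <- function(genotype, model = c("additive", "recessive", "dominant"),
                            major_allele, minor_allele = NULL) {
  model <- match.arg(model)
  al <- parse_genotypes(genotype)
  nmaj <- ifelse(is.na(al$a1), NA_integer_,
                 (al$a1 == major_allele) + (al$a2 == major_allele))
  seen <- stats::na.omit(unique(c(al$a1, al$a2)))
  allowed <- c(major_allele, minor_allele)
  if (is.null(minor_allele)) {
    other <- setdiff(seen, major_allele)
    if (length(other) > 1L)
      stop("more than two alleles observed: ", paste(sort(seen), collapse = ", "))
  } else if (length(setdiff(seen, allowed))) {
    stop("allele not in {major, minor}: ",
         paste(setdiff(seen, allowed), collapse = ", "))
  }
  switch(model,
         additive = as.numeric(nmaj),
         recessive = as.numeric(nmaj == 2L),
         dominant = as.numeric(nmaj >= 1L))
}

parse_genotypes <- function(genotype) {
  g <- as.character(genotype)
  g[!is.na(g) & !nzchar(g)] <- NA_character_
  g2 <- gsub("/", "", g, fixed = TRUE)
  bad <- !is.na(g2) & nchar(g2) != 2L
  if (any(bad)) stop("unparseable genotype: ", paste(unique(g[bad]), collapse = ", "))
  list(a1 = substr(g2, 1, 1), a2 = substr(g2, 2, 2))
}

# Major allele of a SNP column in a genotype-phenotype table; ties broken by
# the reference allele when known (attribute "ref_alleles"), else
# alphabetically with a warning.
major_allele_of <- function(table, snp) {
  al <- parse_genotypes(table[[snp]])
  counts <- sort(table(c(al$a1, al$a2)), decreasing = TRUE)
  if (length(counts) == 1L) return(names(counts))
  if (counts[1] > counts[2]) return(names(counts)[1])
  tied <- names(counts)[counts == counts[1]]
  refs <- attr(table, "ref_alleles")
  if (!is.null(refs) && !is.na(refs[snp]) && refs[[snp]] %in% tied)
    return(refs[[snp]])
  warning("major-allele tie at ", snp, "; using alphabetical order")
  sort(tied)[1]
}

#' Drop monomorphic SNPs from an association panel
#'
#' SNPs with a single observed allele carry no information and are removed
#' (with a message naming them).
#'
#' @param table genotype-phenotype data.frame.
#' @param snps candidate SNP column names.
#' @return the retained SNP names.
#' @export
drop_monomorphic <- function(table, snps) {
  keep <- vapply(snps, function(s) {
    al <- parse_genotypes(table[[s]])
    length(stats::na.omit(unique(c(al$a1, al$a2)))) >= 2L
  }, logical(1))
  if (any(!keep))
    message("dropping monomorphic SNP(s): ", paste(snps[!keep], collapse = ", "))
  snps[keep]
}

#' Linear genotype-phenotype association (horn size)
#'
#' Ordinary least squares of horn length on the model-coded genotype, with
#' optional age and sex covariates (sex entered as a male indicator). Rows
#' with any missing field are excluded listwise.
#'
#' @param table genotype-phenotype data.frame with columns `horn_length`,
#'   `age`, `sex` and the SNP columns.
#' @param snp SNP column name.
#' @param model genetic model for [encode_genotype()].
#' @param covariates subset of `c("age", "sex")`.
#' @param major_allele optional override of the cohort-derived major allele.
#' @return one-row data.frame (`AssocResult`): snp, model, outcome, beta, se,
#'   p_value, n_used, covariates.
#' @export
linear_assoc <- function(table, snp, model = "additive",
                         covariates = c("age", "sex"), major_allele = NULL) {
  if (is.null(major_allele)) major_allele <- major_allele_of(table, snp)
  code <- encode_genotype(table[[snp]], model, major_allele)
  df <- data.frame(y = table$horn_length, code = code)
  if ("age" %in% covariates) df$age <- table$age
  if ("sex" %in% covariates) df$sex <- as.integer(table$sex == "M")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  npar <- ncol(df)  # intercept + code + covariates
  if (nrow(df) < npar + 2L)
    stop("too few complete rows (", nrow(df), ") for ", npar + 1L, " parameters")
  if (stats::var(df$code) == 0)
    stop("singular design: genotype code is constant for ", snp,
         " under the ", model, " model")
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  data.frame(snp = snp, model = model, outcome = "size",
             beta = cf["code", 1], se = cf["code", 2],
             p_value = cf["code", 4], n_used = nrow(df),
             covariates = paste(covariates, collapse = "+"),
             major_allele = major_allele)
}

#' Logistic genotype-phenotype association (horn shape)
#'
#' Maximum-likelihood logistic regression of SHE-type (1) versus TCF-type (0)
#' horn shape on the model-coded genotype, fitted by iteratively reweighted
#' least squares; other shape categories are excluded. Complete separation is
#' flagged as an error with no estimate.
#'
#' @inheritParams linear_assoc
#' @export
logistic_assoc <- function(table, snp, model = "recessive",
                           covariates = character(0), major_allele = NULL) {
  sel <- table$horn_shape %in% c("SHE", "TCF")
  tab <- table[sel, , drop = FALSE]
  if (is.null(major_allele)) major_allele <- major_allele_of(tab, snp)
  code <- encode_genotype(tab[[snp]], model, major_allele)
  df <- data.frame(y = as.integer(tab$horn_shape == "SHE"), code = code)
  if ("age" %in% covariates) df$age <- tab$age
  if ("sex" %in% covariates) df$sex <- as.integer(tab$sex == "M")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2L) stop("both outcome classes must be present")
  if (stats::var(df$code) == 0)
    stop("singular design: genotype code is constant for ", snp,
         " under the ", model, " model")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm's numeric warning is not raised for every separated design; a diverging
  # linear predictor is the reliable symptom
  if (sep || !fit$converged || max(abs(fit$linear.predictors)) > 20)
    stop("complete separation: no maximum-likelihood estimate for ", snp)
  cf <- summary(fit)$coefficients
  data.frame(snp = snp, model = model, outcome = "shape",
             beta = cf["code", 1], se = cf["code", 2],
             p_value = cf["code", 4], n_used = nrow(df),
             covariates = paste(covariates, collapse = "+"),
             major_allele = major_allele)
}

#' Grid of association fits across SNPs, models and outcomes
#'
#' Runs every SNP x model x outcome combination; per-fit failures (e.g. an
#' absent aa class making the dominant code constant, or complete separation)
#' are recorded as skip rows with the reason rather than aborting the grid.
#' A Benjamini-Hochberg adjusted p-value column is appended per outcome as an
#' optional extra.
#'
#' @param table genotype-phenotype data.frame.
#' @param snps SNP column names.
#' @param models genetic models to fit.
#' @param outcomes subset of `c("size", "shape")`.
#' @param covariates covariates for the size (linear) fits; shape fits use
#'   `shape_covariates`.
#' @param shape_covariates covariates for the logistic fits.
#' @return data.frame of results in deterministic (snp, model, outcome) order
#'   with a `note` column ("" or the skip reason).
#' @export
assoc_scan <- function(table, snps, models = c("additive", "recessive", "dominant"),
                       outcomes = c("size", "shape"),
                       covariates = c("age", "sex"),
                       shape_covariates = character(0)) {
  rows <- list()
  for (snp in snps) for (model in models) for (outc in outcomes) {
    res <- tryCatch({
      if (outc == "size")
        linear_assoc(table, snp, model, covariates)
      else
        logistic_assoc(table, snp, model, shape_covariates)
    }, error = function(e) {
      data.frame(snp = snp, model = model, outcome = outc,
                 beta = NA_real_, se = NA_real_, p_value = NA_real_,
                 n_used = NA_integer_, covariates = "",
                 major_allele = NA_character_, note = conditionMessage(e))
    })
    if (is.null(res$note)) res$note <- ""
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(snp = character(0), model = character(0),
                      outcome = character(0), beta = numeric(0),
                      se = numeric(0), p_value = numeric(0),
                      n_used = integer(0), covariates = character(0),
                      major_allele = character(0), note = character(0),
                      p_bh = numeric(0)))
  out$p_bh <- NA_real_
  for (oc in unique(out$outcome)) {
    i <- out$outcome == oc
    out$p_bh[i] <- stats::p.adjust(out$p_value[i], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Read a genotype-phenotype TSV
#'
#' Expects columns `animal_id`, `horn_length`, `horn_shape`, `age`, `sex` and
#' one column per SNP; validates the closed shape-category set.
#'
#' @param path TSV file.
#' @export
read_genopheno <- function(path) {
  df <- read_table_tsv(path)
  need <- c("animal_id", "horn_length", "horn_shape", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$horn_shape),
                 c("polled", "scurred", "TCF", "SHE", "uncertain", NA))
  if (length(bad)) stop("unknown horn-shape category: ", paste(bad, collapse = ", "))
  if (any(df$horn_length < 0, na.rm = TRUE)) stop("negative horn length")
  df
}
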