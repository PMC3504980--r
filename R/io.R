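#' Read a trio genotype file
#'
#' Reads the tab-separated trio format: header
#' `family_id  mother_locus1  father_locus1  child_locus1  mother_locus2`,
#' one family per row, genotypes coded 0/1/2 as risk-allele counts with
#' `NA` (case-insensitive) for missing, `#` comment lines ignored.
#'
#' Rows whose observed genotypes are Mendelian-inconsistent are collected
#' into the validation report with their line numbers and excluded from
#' the returned families (with a warning); they are never silently
#' dropped.  A malformed header, invalid genotype codes, duplicated family
#' ids or an empty file are errors.
#'
#' @param path file path.
#' @return A list with `trios` (valid families, with diagnostic columns
#'   `class` — FULL, CASE_MOTHER, CASE_FATHER or CASE_ONLY — and
#'   `n_compatible_cells`) and `report` (a data frame of rejected rows
#'   with line numbers and the problem found).
#' @export
read_trio_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no families: file is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("family_id", "mother_locus1", "father_locus1",
                "child_locus1", "mother_locus2")
  if (!identical(trimws(header), expected))
    stop("malformed header; expected: ", paste(expected, collapse = ", "))
  if (length(lines) < 2) stop("no families: file has a header but no rows")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  body_lines <- line_no[-1]
  bad_len <- lengths(body) != 5
  if (any(bad_len))
    stop("malformed row(s) at line(s) ",
         paste(body_lines[bad_len], collapse = ", "),
         ": expected 5 tab-separated fields")
  m <- do.call(rbind, body)
  parse_geno <- function(v, col) {
    v <- trimws(v)
    out <- suppressWarnings(as.integer(v))
    is_na <- toupper(v) == "NA"
    ok <- is_na | (!is.na(out) & out %in% 0:2)
    if (!all(ok))
      stop("invalid genotype value(s) in '", col, "' at line(s) ",
           paste(body_lines[!ok], collapse = ", "))
    out[is_na] <- NA_integer_
    out
  }
  fam <- data.frame(
    family_id = trimws(m[, 1]),
    mother_locus1 = parse_geno(m[, 2], "mother_locus1"),
    father_locus1 = parse_geno(m[, 3], "father_locus1"),
    child_locus1 = parse_geno(m[, 4], "child_locus1"),
    mother_locus2 = parse_geno(m[, 5], "mother_locus2"))
  if (anyDuplicated(fam$family_id))
    stop("duplicate family_id values: ",
         paste(unique(fam$family_id[duplicated(fam$family_id)]), collapse = ", "))
  if (anyNA(fam$child_locus1))
    stop("missing child genotypes are not supported; line(s) ",
         paste(body_lines[is.na(fam$child_locus1)], collapse = ", "))
  n_compat <- vapply(seq_len(nrow(fam)), function(r)
    length(compatible_cells(fam$mother_locus1[r], fam$father_locus1[r],
                            fam$child_locus1[r], fam$mother_locus2[r])),
    integer(1))
  bad <- n_compat == 0
  report <- data.frame(line = body_lines[bad],
                       family_id = fam$family_id[bad],
                       problem = rep("Mendelian-inconsistent genotypes", sum(bad)))
  if (any(bad))
    warning(sum(bad), " Mendelian-inconsistent famil",
            if (sum(bad) == 1) "y" else "ies",
            " excluded (see the validation report); line(s) ",
            paste(body_lines[bad], collapse = ", "))
  fam <- fam[!bad, , drop = FALSE]
  if (nrow(fam) == 0) stop("no families: all rows failed validation")
  fam$class <- classify_families(fam)
  fam$n_compatible_cells <- n_compat[!bad]
  rownames(fam) <- NULL
  list(trios = fam, report = report)
}

#' Write a trio genotype file
#'
#' @param trios trio data frame (see [read_trio_file()] for the format).
#' @param path output file path.
#' @export
write_trio_file <- function(trios, path) {
  trios <- validate_trios(as.data.frame(trios))
  cols <- c("family_id", "mother_locus1", "father_locus1",
            "child_locus1", "mother_locus2")
  out <- trios[, cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize fit results
#'
#' `write_effects_table()` writes the per-effect inference table (relative
#' risks, 95% CIs, likelihood-ratio tests) as tab-separated text;
#' `write_fit_json()` writes a machine-readable record of the fit
#' (coefficients, covariance, log-likelihood, convergence, data summary).
#'
#' @param fit a fitted [trio_model()].
#' @param path output path.
#' @export
write_effects_table <- function(fit, path) {
  eff <- suppressWarnings(summary(fit))$effects
  utils::write.table(eff, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_effects_table
#' @export
write_fit_json <- function(fit, path) {
  rec <- list(
    variant = fit$spec$variant,
    effects = fit$spec$effects,
    coding = fit$spec$coding,
    specified_p = fit$spec$p,
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    em = fit$em,
    n_em_iterations = if (fit$em) fit$em_info$n_em_iter else 0L,
    not_estimable = fit$not_estimable,
    data_summary = fit$data_summary)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study configuration file
#'
#' YAML (or JSON) description of a Monte-Carlo study: fields `model` (or a
#' `risk`/`pop` pair is not supported in configs), `n_families`,
#' `n_replicates`, `seed`, `alpha`, `variant`, `coding`, `effects`,
#' `effects_to_test`, `p`, `missing_father_rate`, `missing_mother_rate`.
#'
#' @param path config file path.
#' @return A named list of study arguments with defaults filled in.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_families = 1000, n_replicates = 1000, seed = 1,
                   alpha = 0.05, variant = "eq1", coding = "dominant",
                   effects = NULL, effects_to_test = NULL, p = NULL,
                   missing_father_rate = 0, missing_mother_rate = 0)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$model)) stop("study config must name a scenario preset 'model'")
  if (cfg$variant %in% c("eq1", "eq1_hwe") && is.null(cfg$p))
    cfg$p <- hwe_genotype_freq(0.3)
  cfg
}
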