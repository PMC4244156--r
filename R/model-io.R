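model_format_version <- 1L

#' Save and load genotype models
#'
#' Models are persisted as a self-describing JSON file carrying the format
#' version, indel kind, feature order, scaler ranges, the winning kernel
#' parameters, and the full-precision training data; loading refits the
#' SVM with the stored parameters (libsvm training is deterministic for
#' fixed data and parameters), so a loaded model reproduces the saved
#' model's predictions exactly. A version or feature-order mismatch is a
#' hard error — silently permuted features are the worst failure mode of a
#' stored classifier.
#'
#' @param model A `genotype_model`.
#' @param path Output `.json` path.
#' @return `save_genotype_model()`: `path`, invisibly;
#'   `read_genotype_model()`: the reconstructed `genotype_model`.
#' @export
save_genotype_model <- function(model, path) {
  obj <- list(
    format = "indelgt_genotype_model",
    format_version = model_format_version,
    package_version = as.character(utils::packageVersion("indelgt")),
    kind = model$kind,
    feature_names = model$feature_names,
    classes = model$classes,
    cost = model$cost, gamma = model$gamma,
    folds = model$folds, seed = model$seed,
    cv_accuracy = model$cv_accuracy,
    class_weights = model$class_weights,
    scaler = list(min = as.numeric(model$scaler$min),
                  max = as.numeric(model$scaler$max)),
    x_train = unname(as.matrix(model$x_train)),
    y_train = model$y_train,
    # decision fields of the fitted libsvm model: restoring these after the
    # refit makes loaded predictions (incl. probabilities, whose training
    # involves libsvm's own RNG) bit-identical to the saved model's
    svm = list(SV = unname(as.matrix(model$svm$SV)),
               nSV = model$svm$nSV,
               tot_nSV = model$svm$tot.nSV,
               labels = model$svm$labels,
               coefs = unname(as.matrix(model$svm$coefs)),
               rho = model$svm$rho,
               probA = model$svm$probA,
               probB = model$svm$probB,
               compprob = model$svm$compprob))
  # digits = I(17): shortest exact decimal for doubles, so numeric state
  # survives the round trip bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_genotype_model
#' @export
read_genotype_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort(paste0("cannot parse model file ", path, ": ",
                                 conditionMessage(e))))
  if (!identical(obj$format, "indelgt_genotype_model"))
    abort(paste0(path, " is not an indelgt genotype model file"))
  if (!identical(as.integer(obj$format_version), model_format_version))
    abort(paste0("model format version ", obj$format_version,
                 " is incompatible with this package (expected ",
                 model_format_version, ")"))
  expected <- feature_names_for(obj$kind)
  if (!identical(as.character(obj$feature_names), expected))
    abort(paste0("model feature order (",
                 paste(obj$feature_names, collapse = ", "),
                 ") does not match this package's ", obj$kind,
                 " order (", paste(expected, collapse = ", "), ")"))
  x <- as.matrix(obj$x_train)
  y <- as.integer(obj$y_train)
  classes <- as.integer(obj$classes)
  scaler <- structure(list(min = as.numeric(obj$scaler$min),
                           max = as.numeric(obj$scaler$max),
                           constant = obj$scaler$max == obj$scaler$min,
                           dim = ncol(x), names = NULL),
                      class = "indel_scaler")
  xs <- apply_scaler(scaler, x)
  yf <- factor(y, levels = classes)
  wts <- if (isTRUE(obj$class_weights))
    stats::setNames(sum(table(yf)) / (nlevels(yf) * table(yf)),
                    levels(yf))
  else NULL
  fit <- e1071::svm(xs, yf, kernel = "radial", cost = obj$cost,
                    gamma = obj$gamma, scale = FALSE, probability = TRUE,
                    class.weights = wts)
  if (!is.null(obj$svm)) {
    fit$SV <- as.matrix(obj$svm$SV)
    fit$nSV <- as.integer(obj$svm$nSV)
    fit$tot.nSV <- as.integer(obj$svm$tot_nSV)
    fit$labels <- as.integer(obj$svm$labels)
    fit$coefs <- as.matrix(obj$svm$coefs)
    fit$rho <- as.numeric(obj$svm$rho)
    fit$probA <- as.numeric(obj$svm$probA)
    fit$probB <- as.numeric(obj$svm$probB)
    fit$compprob <- isTRUE(obj$svm$compprob)
  }
  structure(list(scaler = scaler, svm = fit, cost = obj$cost,
                 gamma = obj$gamma, folds = as.integer(obj$folds),
                 seed = as.integer(obj$seed),
                 cv_accuracy = obj$cv_accuracy, cv_table = NULL,
                 kind = obj$kind, feature_names = expected,
                 classes = classes,
                 class_weights = isTRUE(obj$class_weights),
                 x_train = x, y_train = y),
            class = "genotype_model")
}

#' Write called genotypes as VCF
#'
#' One record per site; per-sample `GT` maps genotype 0/1/2 to 0/0, 0/1,
#' 1/1, with genotype probabilities in a `GP` FORMAT field when present.
#' The header records the package version and a digest of the run
#' configuration, so outputs are traceable to their settings.
#'
#' @param calls Call tibble from [call_genotypes()] (with `sample` and
#'   `site_id`).
#' @param sites Site tibble.
#' @param path Output `.vcf` path.
#' @param config Optional list of run settings to digest into the header.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, sites, path, config = NULL) {
  if (!all(c("sample", "site_id", "genotype") %in% names(calls)))
    abort("calls must have sample, site_id and genotype columns")
  unknown <- setdiff(unique(calls$site_id), sites$site_id)
  if (base::length(unknown) > 0)
    abort(paste0("calls reference unknown site id(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  smps <- sort(unique(calls$sample))
  with_probs <- all(c("p0", "p1", "p2") %in% names(calls))
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  cells <- calls %>%
    mutate(cell = if (with_probs)
      paste0(gt_map[as.character(.data$genotype)], ":",
             sprintf("%.4f,%.4f,%.4f", .data$p0, .data$p1, .data$p2))
      else gt_map[as.character(.data$genotype)]) %>%
    select("sample", "site_id", "cell") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "cell",
                       values_fill = if (with_probs) "./.:." else "./.")
  used <- sites %>% filter(.data$site_id %in% cells$site_id)
  cells <- cells[match(used$site_id, cells$site_id), , drop = FALSE]
  digest <- if (is.null(config)) "none" else rlang::hash(config)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=indelgt-",
                  utils::packageVersion("indelgt")),
           paste0("##indelgt_config_digest=", digest),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (with_probs)
             "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities for 0/0, 0/1, 1/1\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", smps), collapse = "\t"))
  svlen <- ifelse(used$kind == "DEL", -used$length, used$length)
  info <- paste0("SVTYPE=", used$kind, ";END=",
                 ifelse(used$kind == "INS", used$p1 + 1L, used$p2),
                 ";SVLEN=", svlen)
  fmt <- if (with_probs) "GT:GP" else "GT"
  body <- paste(used$chrom, used$p1 + 1L, used$site_id, "N",
                ifelse(used$kind == "DEL", "<DEL>", "<INS>"), ".", "PASS",
                info, fmt,
                apply(as.matrix(cells[, smps, drop = FALSE]), 1, paste,
                      collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
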