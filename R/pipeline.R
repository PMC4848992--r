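# End-to-end orchestration: fixture -> descriptors -> SW-MLR -> validation
# -> applicability domain -> alignment -> field model -> designed-compound
# prediction, with a machine-readable report.

#' Run the full study analysis
#'
#' Two modes, reported side by side in practice:
#' \describe{
#'   \item{`"printed"`}{statistics are computed from the fixture's shipped
#'     prediction columns (`pred_mlr`, `pred_comfa`); this reproduces the
#'     reference statistics exactly and needs no structure handling.}
#'   \item{`"refit"`}{descriptors are recomputed with the package's own
#'     engine, the five-descriptor model is refitted (optionally after
#'     stepwise selection), validation / applicability domain are computed
#'     from the refit, and, when `with_3d`, the compounds are aligned on
#'     the most active molecule and a field-PLS model is trained.
#'     Descriptor engines differ, so these statistics are expected to
#'     differ from the reference ones.}
#' }
#'
#' @param mode `"printed"` or `"refit"`.
#' @param table an `activity_table`; defaults to the packaged fixture.
#' @param seed integer seed for every random stage.
#' @param with_3d logical; in refit mode also build the 3D field model.
#' @param stepwise logical; in refit mode run stepwise selection over the
#'   five descriptors instead of using all of them.
#' @param spacing,sigma_min,max_components field-model settings.
#' @param out_dir optional directory for per-stage artifacts (CSV/JSON).
#' @return a list of class `study_report` with elements `mode`, `mlr`
#'   (validation report), `model`, `ad` (leverage report), `comfa`
#'   (PLS summary, refit+3d mode), `provenance`.
#' @export
run_study <- function(mode = c("printed", "refit"), table = aad_compounds(),
                      seed = 1L, with_3d = FALSE, stepwise = FALSE,
                      spacing = 2.0, sigma_min = 6.0, max_components = 10L,
                      out_dir = NULL) {
  mode <- match.arg(mode)
  tr <- table$split == "train"
  report <- list(mode = mode,
                 provenance = list(seed = seed, n_train = sum(tr),
                                   n_test = sum(!tr)))
  if (mode == "printed") {
    if (is.null(table$pred_mlr) || is.null(table$pred_comfa))
      stop("printed mode needs pred_mlr and pred_comfa columns")
    report$mlr <- validation_report(table$pec50[tr], table$pred_mlr[tr],
                                    table$pec50[!tr], table$pred_mlr[!tr],
                                    p = 5L)
    report$comfa <- validation_report(table$pec50[tr], table$pred_comfa[tr],
                                      table$pec50[!tr], table$pred_comfa[!tr],
                                      p = 4L)
    report$h_star <- warning_leverage(5L, sum(tr))
    report$max_abs_std_residual_train <- max(abs(standardized_residuals(
      table$pec50[tr], table$pred_mlr[tr],
      rmse(table$pec50[tr], table$pred_mlr[tr]))))
  } else {
    desc <- compute_descriptor_matrix(table, seed = seed)
    y <- table$pec50
    # a descriptor that is constant over the training compounds (the
    # Oprea flag often is, within a congeneric series) cannot enter a
    # regression and is dropped with a message
    keep <- vapply(desc[tr, , drop = FALSE], stats::sd, 1.0) > 0
    if (!all(keep))
      message("dropping constant descriptor(s): ",
              paste(names(desc)[!keep], collapse = ", "))
    desc_v <- desc[, keep, drop = FALSE]
    if (stepwise) {
      sw <- stepwise_select(desc_v[tr, ], y[tr])
      if (!length(sw$selected)) stop("stepwise selected no descriptors")
      model <- sw$model
      desc_used <- desc_v[, sw$selected, drop = FALSE]
    } else {
      model <- fit_ols(desc_v[tr, ], y[tr])
      desc_used <- desc_v
    }
    pred <- predict(model, desc_used)
    report$descriptors <- desc
    report$model <- model
    report$mlr <- validation_report(y[tr], pred[tr], y[!tr], pred[!tr],
                                    p = model$p,
                                    X_train = desc_used[tr, , drop = FALSE])
    report$yrand <- y_randomization(desc_used[tr, , drop = FALSE], y[tr],
                                    k = 10L, seed = seed)
    report$ad <- williams_report(desc_used, y, pred, table$split)
    if (with_3d) {
      comfa <- fit_field_model(table, seed = seed, spacing = spacing,
                               sigma_min = sigma_min,
                               max_components = max_components)
      report$comfa <- comfa
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeable <- report
    writeable$model <- if (!is.null(report$model))
      serialize_mlr(report$model) else NULL
    writeable$comfa <- if (!is.null(report$comfa) &&
                           inherits(report$comfa, "field_model_fit"))
      report$comfa$summary else writeable$comfa
    writeable$descriptors <- NULL
    writeable$ad <- if (!is.null(report$ad)) report$ad$table else NULL
    jsonlite::write_json(writeable, file.path(out_dir, "study_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    if (!is.null(report$descriptors))
      write_descriptor_matrix(report$descriptors,
                              file.path(out_dir, "descriptors.csv"))
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", x$mode, " mode)\n", sep = "")
  cat("-- MLR --\n"); print(x$mlr)
  if (!is.null(x$comfa) && inherits(x$comfa, "validation_report")) {
    cat("-- CoMFA (printed) --\n"); print(x$comfa)
  }
  invisible(x)
}

#' Align the series and fit the 3D field-PLS model
#'
#' Generates one conformer per compound, maps each onto the template (the
#' most active compound) by maximum-common-scaffold matching, rigidly
#' aligns, builds the lattice and field matrix, filters columns, selects
#' the component count by LOO Q2 on the training compounds, and fits the
#' final PLS model.
#'
#' @param table an `activity_table`.
#' @param template_id id of the alignment template; defaults to the most
#'   active (highest pEC50) compound.
#' @param seed,spacing,sigma_min,max_components settings.
#' @return a list of class `field_model_fit`: `model` (`pls_field_model`),
#'   `block`, `conformers`, `rmsd` (per-compound alignment RMSD),
#'   `validation` (train/test statistics), `summary`.
#' @export
fit_field_model <- function(table, template_id = NULL, seed = 1L,
                            spacing = 2.0, sigma_min = 6.0,
                            max_components = 10L) {
  if (is.null(template_id)) template_id <- table$id[which.max(table$pec50)]
  ti <- match(template_id, table$id)
  if (is.na(ti)) stop("template id not in table")
  mols <- parse_structures(table$structure, gen3d = TRUE, seed = seed)
  tmpl_mol <- mols[[ti]]
  tmpl <- as_conformer(tmpl_mol)
  n <- nrow(table)
  conformers <- vector("list", n); rmsd <- numeric(n)
  for (k in seq_len(n)) {
    if (k == ti) { conformers[[k]] <- tmpl; next }
    mol <- mols[[k]]
    conf <- as_conformer(mol)
    mapping <- common_scaffold_mapping(mol, tmpl_mol)
    al <- align_to_template(conf, tmpl, mapping)
    conformers[[k]] <- al$conformer
    rmsd[k] <- al$rmsd
  }
  names(conformers) <- table$id
  lattice <- build_lattice(conformers, spacing = spacing)
  block <- field_block(conformers, lattice)
  tr <- table$split == "train"
  block_tr <- unclass(block)[tr, , drop = FALSE]
  for (a in c("lattice", "field", "point", "retained"))
    attr(block_tr, a) <- attr(block, a)
  class(block_tr) <- class(block)
  block_tr <- column_filter(block_tr, sigma_min)
  attr(block, "retained") <- attr(block_tr, "retained")
  sel <- select_components(block_tr, table$pec50[tr],
                           max_components = max_components)
  model <- fit_pls(block_tr, table$pec50[tr], sel$n_components)
  pred <- predict(model, block)
  val <- validation_report(table$pec50[tr], pred[tr],
                           table$pec50[!tr], pred[!tr],
                           p = sel$n_components)
  structure(list(model = model, block = block, conformers = conformers,
                 template_id = template_id,
                 template_structure = table$structure[ti],
                 rmsd = rmsd, q2_loo = sel$q2, validation = val,
                 summary = list(
                   n_components = sel$n_components, q2_loo = sel$q2,
                   r2_train = val$r2_train, rmse_train = val$rmse_train,
                   r2_test = val$r2_test, rmse_test = val$rmse_test,
                   contributions = as.list(model$contributions))),
            class = "field_model_fit")
}

#' Predict the designed compounds
#'
#' Computes the package-engine descriptors of the designed analogues and
#' runs them through a fixed linear model (by default the reference
#' coefficient set, [aad_reference_mlr()]); optionally also through a
#' fitted field model. Reference predicted values shipped with the table
#' are carried along for comparison — no numeric agreement is implied,
#' since descriptor engines differ.
#'
#' @param table data frame of designed compounds (default [aad_designed()]).
#' @param mlr a list with `coefficients` and `intercept` (default the
#'   reference coefficient set) or an `mlr_model`.
#' @param field_fit optional `field_model_fit`; adds field-model
#'   predictions (compounds are aligned onto its template).
#' @param seed integer seed.
#' @return the table with a `pred_mlr_engine` column (and
#'   `pred_field_engine` when a field model is given), ranked by the new
#'   prediction.
#' @export
predict_designed <- function(table = aad_designed(),
                             mlr = aad_reference_mlr(),
                             field_fit = NULL, seed = 1L) {
  desc <- compute_descriptor_matrix(table, seed = seed)
  if (inherits(mlr, "mlr_model")) {
    cf <- mlr$coefficients; ic <- mlr$intercept
  } else {
    cf <- mlr$coefficients; ic <- mlr$intercept
  }
  table$pred_mlr_engine <- predict_mlr(cf, ic, desc)
  if (!is.null(field_fit)) {
    tmpl_conf <- field_fit$conformers[[field_fit$template_id]]
    tmpl_mol <- parse_structure(field_fit$template_structure, gen3d = TRUE)
    lattice <- attr(field_fit$block, "lattice")
    preds <- numeric(nrow(table))
    for (k in seq_len(nrow(table))) {
      mol <- parse_structure(table$structure[k], gen3d = TRUE)
      conf <- as_conformer(mol)
      mapping <- tryCatch(common_scaffold_mapping(mol, tmpl_mol),
                          error = function(e) NULL)
      if (!is.null(mapping) && nrow(mapping) >= 3L)
        conf <- align_to_template(conf, tmpl_conf, mapping)$conformer
      b <- field_block(list(conf), lattice)
      preds[k] <- predict(field_fit$model, b)
    }
    table$pred_field_engine <- preds
  }
  table[order(-table$pred_mlr_engine), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an MLR model to a JSON-ready list / JSON file
#'
#' @param model an `mlr_model`.
#' @param path optional file path; when given the JSON is written there.
#' @return the plain list (invisibly when written to file).
#' @export
serialize_mlr <- function(model, path = NULL) {
  out <- list(descriptor_names = model$descriptor_names,
              coefficients = as.list(model$coefficients),
              se = as.list(model$se),
              intercept = model$intercept,
              intercept_se = model$intercept_se,
              standardized_coefficients = as.list(model$std_coefficients),
              n_train = model$n_train, r2 = model$r2, rmse = model$rmse,
              f_stat = model$f_stat)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
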