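# Activity tables: EC50 <-> pEC50 conversion, CSV I/O, the packaged
# 41-compound fixture and the designed-compound set.

#' Convert an EC50 in micromolar to pEC50
#'
#' pEC50 is the negative decadic logarithm of the molar EC50; for a
#' concentration given in micromolar this is `6 - log10(ec50_uM)`.
#'
#' @param ec50_uM positive EC50 value(s) in micromolar.
#' @return pEC50 value(s).
#' @seealso [ec50_from_pec50()] for the inverse.
#' @export
#' @examples
#' pec50_from_ec50(0.28)  # 6.553
#' pec50_from_ec50(1.0)   # 6
pec50_from_ec50 <- function(ec50_uM) {
  if (!is.numeric(ec50_uM) || any(!is.finite(ec50_uM)) || any(ec50_uM <= 0))
    stop("ec50_uM must be positive and finite")
  6 - log10(ec50_uM)
}

#' @rdname pec50_from_ec50
#' @param pec50 pEC50 value(s).
#' @export
ec50_from_pec50 <- function(pec50) {
  if (!is.numeric(pec50) || any(!is.finite(pec50)))
    stop("pec50 must be finite")
  10^(6 - pec50)
}

#' Load and validate an activity table
#'
#' Reads a one-compound-per-row CSV with columns `id`, `structure` and at
#' least one of `ec50_uM` / `pec50`; optional columns `split`
#' (`train`/`test`, default `train`), `pred_mlr` and `pred_comfa`.
#' Validates id uniqueness, structure parseability (cheap syntactic check),
#' EC50 positivity and, when both activity columns are present, their
#' logarithmic consistency to 0.001.
#'
#' @param path CSV file path.
#' @param check_structures logical; parse every structure with Open Babel
#'   (slower, default TRUE).
#' @return a data frame of class `activity_table`.
#' @export
load_activity_table <- function(path, check_structures = TRUE) {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  need <- c("id", "structure")
  if (!all(need %in% names(d)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  if (!any(c("ec50_uM", "pec50") %in% names(d)))
    stop("activity table needs an 'ec50_uM' or 'pec50' column")
  dup <- unique(d$id[duplicated(d$id)])
  if (length(dup))
    stop("duplicate compound id(s): ", paste(dup, collapse = ", "))
  if (!is.null(d$ec50_uM)) {
    bad <- which(!is.na(d$ec50_uM) & d$ec50_uM <= 0)
    if (length(bad))
      stop("non-positive EC50 for id(s): ", paste(d$id[bad], collapse = ", "))
  }
  if (is.null(d$pec50)) d$pec50 <- pec50_from_ec50(d$ec50_uM)
  miss <- which(is.na(d$pec50))
  if (length(miss)) {
    if (is.null(d$ec50_uM) || anyNA(d$ec50_uM[miss]))
      stop("no activity available for id(s): ",
           paste(d$id[miss], collapse = ", "))
    d$pec50[miss] <- pec50_from_ec50(d$ec50_uM[miss])
  }
  if (!is.null(d$ec50_uM)) {
    both <- which(!is.na(d$ec50_uM))
    off <- abs(d$pec50[both] - pec50_from_ec50(d$ec50_uM[both])) > 0.001
    if (any(off))
      stop("pec50 and ec50_uM disagree for id(s): ",
           paste(d$id[both][off], collapse = ", "))
  }
  if (is.null(d$split)) d$split <- "train"
  d$split[is.na(d$split) | d$split == ""] <- "train"
  if (!all(d$split %in% c("train", "test")))
    stop("split must be 'train' or 'test'")
  if (check_structures) {
    for (k in seq_len(nrow(d))) {
      ok <- tryCatch({ parse_structure(d$structure[k]); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop("unparsable structure for id ", d$id[k], ": '",
                    d$structure[k], "'")
    }
  }
  class(d) <- c("activity_table", "data.frame")
  d
}

#' The packaged anthranilic-acid FXR agonist series
#'
#' Activity table of the 41 modelled compounds: R-group annotations, SMILES
#' encodings of the structures, experimental EC50 (micromolar) and pEC50,
#' the train/test split (31/10) and the reference predictions of the
#' five-descriptor MLR model (`pred_mlr`) and of the CoMFA model
#' (`pred_comfa`).
#'
#' @param check_structures logical; see [load_activity_table()]. The fixture
#'   is pre-validated, so the default skips the slow structure check.
#' @return an `activity_table` data frame with 41 rows.
#' @export
aad_compounds <- function(check_structures = FALSE) {
  path <- system.file("extdata", "aad_activity.csv", package = "anthraqsar",
                      mustWork = TRUE)
  load_activity_table(path, check_structures = check_structures)
}

#' The designed analogues and their template
#'
#' Nine designed compounds (N1-N9) plus the template compound (T30, the most
#' active molecule of the series), with SMILES encodings and the reference
#' predicted pEC50 values of the MLR and CoMFA models.
#'
#' @return a data frame with 10 rows.
#' @export
aad_designed <- function() {
  path <- system.file("extdata", "aad_designed.csv", package = "anthraqsar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an activity table to CSV
#' @param table an `activity_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_activity_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
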