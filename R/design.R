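# Shared design-matrix construction. Factors (and character columns) are
# reference-coded with the first level alphabetically as the reference, so
# simulator coefficient names, fitted coefficient names and prediction
# designs always agree.
build_design <- function(data, terms) {
  if (length(terms) == 0L)
    return(matrix(1, nrow(data), 1L,
                  dimnames = list(NULL, "(Intercept)")))
  missing <- setdiff(terms, names(data))
  if (length(missing))
    stop("covariates not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- data[, terms, drop = FALSE]
  for (j in names(df)) {
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    if (is.factor(df[[j]])) df[[j]] <- factor(df[[j]], levels = sort(levels(df[[j]])))
  }
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = df)
}

# Match a named coefficient vector to design columns; every design column
# (other than those the caller allows to default to zero) must be named.
align_coefs <- function(coefs, design, label) {
  cols <- colnames(design)
  out <- setNames(numeric(length(cols)), cols)
  unknown <- setdiff(names(coefs), cols)
  if (length(unknown))
    stop(label, " coefficients do not match design columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out[names(coefs)] <- coefs
  out
}
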