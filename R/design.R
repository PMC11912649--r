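# Shared design-matrix construction.  All models (count and Cox) and the
# simulator map covariates to columns through this one helper so that
# coefficient names agree everywhere: binary covariates keep their name,
# categorical covariates expand to treatment contrasts against the first
# declared level (columns "<name><level>"), continuous covariates keep
# their name.

build_design <- function(data, schema, covariates, intercept = FALSE) {
  if (length(covariates) == 0) {
    mm <- matrix(numeric(0), nrow = nrow(data), ncol = 0)
    if (intercept) {
      mm <- cbind("(Intercept)" = rep(1, nrow(data)))
    }
    return(mm)
  }
  miss <- setdiff(covariates, names(schema))
  if (length(miss) > 0) {
    stop("unknown covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, covariates, drop = FALSE]
  for (nm in covariates) {
    decl <- schema[[nm]]
    if (decl$type == "categorical") {
      v <- as.character(df[[nm]])
      extra <- setdiff(unique(v[!is.na(v)]), decl$levels)
      if (length(extra) > 0) {
        stop("covariate '", nm, "': unknown level(s) ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      df[[nm]] <- factor(v, levels = decl$levels)
    }
  }
  fml <- stats::as.formula(paste(
    "~", if (intercept) "" else "0 +",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  mm <- stats::model.matrix(fml, data = df)
  # drop reference-level columns model.matrix keeps when intercept is absent
  if (!intercept) {
    keep <- rep(TRUE, ncol(mm))
    for (nm in covariates) {
      decl <- schema[[nm]]
      if (decl$type == "categorical") {
        ref_col <- paste0(nm, decl$levels[1])
        keep[colnames(mm) == ref_col] <- FALSE
      }
    }
    mm <- mm[, keep, drop = FALSE]
  }
  colnames(mm) <- gsub("`", "", colnames(mm), fixed = TRUE)
  attr(mm, "assign") <- NULL
  attr(mm, "contrasts") <- NULL
  mm
}

# Linear predictor from a named coefficient map over design columns.
# Coefficient names must be a subset of the design's column names;
# "(Intercept)" is honoured when present in both.
linear_predictor <- function(X, coefs) {
  if (length(coefs) == 0) return(rep(0, nrow(X)))
  miss <- setdiff(names(coefs), colnames(X))
  if (length(miss) > 0) {
    stop("coefficient(s) with no matching design column: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  drop(X[, names(coefs), drop = FALSE] %*% unname(coefs))
}
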