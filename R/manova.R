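#' Pillai's trace from hypothesis and error cross-product matrices
#'
#' V = trace(H (H + E)^-1), the sum of the eigenvalues of H(H+E)^-1.
#' In the univariate limit (1 response) this reduces to SSB/SST, the R^2
#' of the hypothesis term.
#'
#' @param H hypothesis sums-of-squares-and-cross-products matrix.
#' @param E error sums-of-squares-and-cross-products matrix.
#' @return Pillai's trace V.
#' @export
pillai_trace <- function(H, E) {
  H <- as.matrix(H); E <- as.matrix(E)
  T_ <- H + E
  qrT <- qr(T_)
  if (qrT$rank < ncol(T_)) stop("singular total cross-product matrix")
  sum(diag(solve(T_, H)))
}

# Pillai approximate F for a hypothesis with q df, p responses, df_error
pillai_f <- function(V, p, q, df_error) {
  s <- min(p, q)
  if (s < 1) return(list(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                         p_value = NA_real_))
  m <- (abs(p - q) - 1) / 2
  n <- (df_error - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Binarise environmental/human covariates
#'
#' Temperature is binarised at 25 deg C, relative humidity at 65% and
#' traveller count at 100; boundary values fall in the low class. Returns
#' the metadata with factor columns `TEMPERATURE`, `HUMIDITY`,
#' `TRAVELLERS` (levels `low`/`high`) added, plus factors `CITY`, `YEAR`,
#' `GROUNDLEVEL`.
#'
#' @param metadata metadata data frame (see [read_metadata()]).
#' @param temp_cut,humidity_cut,travellers_cut binarisation thresholds.
#' @return metadata with the covariate factor columns appended.
#' @export
binarise_covariates <- function(metadata, temp_cut = 25, humidity_cut = 65,
                                travellers_cut = 100) {
  bin <- function(x, cut) {
    factor(ifelse(is.na(x), NA, ifelse(x > cut, "high", "low")),
           levels = c("low", "high"))
  }
  out <- metadata
  out$CITY <- factor(metadata$city)
  out$YEAR <- factor(metadata$year)
  out$TEMPERATURE <- bin(metadata$temperature, temp_cut)
  out$HUMIDITY <- bin(metadata$humidity, humidity_cut)
  out$TRAVELLERS <- bin(metadata$travellers, travellers_cut)
  out$GROUNDLEVEL <- factor(metadata$ground_level, levels = c("above", "below"))
  out
}

#' Forward-stepwise MANOVA on Pillai's trace
#'
#' Starting from an intercept-only multivariate model on the PC score
#' matrix, each remaining candidate term is tentatively added and its
#' partial Pillai trace (hypothesis cross-products from the drop in
#' residual cross-products, error from the enlarged model) is converted
#' to an approximate F. The candidate with the largest F enters if its
#' p-value is below `alpha`; selection stops when no candidate qualifies.
#' Interaction terms `CITY:X` become eligible only once both `CITY` and
#' `X` are in the model (hierarchy). Rows with a missing value in any
#' candidate covariate are dropped once, up front; candidates with fewer
#' than two observed levels are skipped.
#'
#' @param scores samples x k matrix of dependent variables (PC scores),
#'   sample ids as row names.
#' @param metadata metadata data frame; covariates are binarised via
#'   [binarise_covariates()] if the factor columns are not yet present.
#' @param candidate_terms character vector of main-effect terms among
#'   `CITY`, `YEAR`, `TEMPERATURE`, `HUMIDITY`, `TRAVELLERS`,
#'   `GROUNDLEVEL`; interactions `CITY:X` are added automatically for
#'   every environmental term unless `interactions = FALSE`.
#' @param alpha inclusion threshold on the term p-value (default 0.001).
#' @param interactions add CITY interactions for environmental terms.
#' @return an object of class `aero_manova`: list with `included` (terms
#'   in inclusion order), `terms` (data frame of the included terms with
#'   Pillai V, F, dfs, p), `steps` (every candidate evaluation at every
#'   step), `n_used`, `n_dropped`, `k`.
#' @export
manova_forward_select <- function(scores, metadata,
                                  candidate_terms = c("CITY", "YEAR",
                                                      "TEMPERATURE",
                                                      "HUMIDITY",
                                                      "TRAVELLERS",
                                                      "GROUNDLEVEL"),
                                  alpha = 0.001, interactions = TRUE) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stop("scores must carry sample ids")
  if (!all(candidate_terms %in% names(metadata))) {
    metadata <- binarise_covariates(metadata)
    missing_terms <- setdiff(candidate_terms, names(metadata))
    if (length(missing_terms) > 0) {
      stop("unknown candidate term(s): ", paste(missing_terms, collapse = ", "))
    }
  }
  meta <- metadata[match(rownames(scores), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for score row(s)")

  main_terms <- candidate_terms
  inter_terms <- character(0)
  if (interactions && "CITY" %in% main_terms) {
    env <- setdiff(main_terms, c("CITY", "YEAR"))
    inter_terms <- paste0("CITY:", env)
  }
  all_terms <- c(main_terms, inter_terms)

  cc <- stats::complete.cases(meta[, main_terms, drop = FALSE])
  n_dropped <- sum(!cc)
  meta <- droplevels(meta[cc, , drop = FALSE])
  Y <- scores[cc, , drop = FALSE]
  p <- ncol(Y)
  n <- nrow(Y)
  if (n <= p + 2) stop("too few complete-case samples (", n,
                       ") for ", p, " response dimensions")

  usable <- vapply(main_terms, function(tm) {
    nlevels(droplevels(meta[[tm]])) >= 2
  }, logical(1))
  skipped <- main_terms[!usable]
  remaining <- c(main_terms[usable],
                 inter_terms[sub("^CITY:", "", inter_terms) %in%
                               main_terms[usable]])

  fit_rss <- function(terms) {
    X <- if (length(terms) == 0) {
      matrix(1, n, 1)
    } else {
      stats::model.matrix(stats::as.formula(
        paste("~", paste(terms, collapse = "+"))), data = meta)
    }
    qx <- qr(X)
    res <- stats::lm.fit(X, Y)$residuals
    list(rss = crossprod(res), rank = qx$rank)
  }

  included <- character(0)
  steps <- list()
  term_rows <- list()
  base <- fit_rss(included)

  repeat {
    eligible <- vapply(remaining, function(tm) {
      if (!grepl(":", tm)) return(TRUE)
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      all(parts %in% included)
    }, logical(1))
    cands <- remaining[eligible]
    if (length(cands) == 0) break
    evals <- lapply(cands, function(tm) {
      full <- tryCatch(fit_rss(c(included, tm)), error = function(e) NULL)
      if (is.null(full)) return(NULL)
      q <- full$rank - base$rank
      if (q < 1) return(NULL)
      E <- full$rss
      H <- base$rss - E
      T_ <- H + E
      if (qr(T_)$rank < ncol(T_)) {
        stop("singular error structure when adding term ", tm,
             " (collinear with the current model)")
      }
      V <- sum(diag(solve(T_, H)))
      df_error <- n - full$rank
      f <- pillai_f(V, p, q, df_error)
      data.frame(step = length(included) + 1, term = tm, pillai = V,
                 F = f$F, df1 = f$df1, df2 = f$df2, p_value = f$p_value,
                 stringsAsFactors = FALSE)
    })
    evals <- do.call(rbind, evals[!vapply(evals, is.null, logical(1))])
    if (is.null(evals) || nrow(evals) == 0) break
    steps[[length(steps) + 1]] <- evals
    qualify <- evals[!is.na(evals$p_value) & evals$p_value < alpha, ,
                     drop = FALSE]
    if (nrow(qualify) == 0) break
    best <- qualify[which.max(qualify$F), , drop = FALSE]
    included <- c(included, best$term)
    term_rows[[length(term_rows) + 1]] <- best
    remaining <- setdiff(remaining, best$term)
    base <- fit_rss(included)
  }

  structure(list(
    included = included,
    terms = if (length(term_rows)) do.call(rbind, term_rows) else
      data.frame(step = integer(), term = character(), pillai = numeric(),
                 F = numeric(), df1 = numeric(), df2 = numeric(),
                 p_value = numeric()),
    steps = if (length(steps)) do.call(rbind, steps) else NULL,
    skipped_constant = skipped,
    n_used = n, n_dropped = n_dropped, k = p, alpha = alpha),
    class = "aero_manova")
}

#' @export
print.aero_manova <- function(x, ...) {
  cat("Forward-stepwise MANOVA (Pillai's trace), alpha =", x$alpha, "\n")
  cat("samples used:", x$n_used, "(", x$n_dropped, "dropped ),",
      "response dims:", x$k, "\n")
  if (length(x$included) == 0) {
    cat("no terms included\n")
  } else {
    print(x$terms, row.names = FALSE)
  }
  invisible(x)
}
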