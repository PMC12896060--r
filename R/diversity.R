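#' Shannon alpha diversity per sample
#'
#' Shannon index H = -sum p_i ln p_i (natural log) over the nonzero
#' proportions of each sample, computed with `vegan::diversity`. H depends
#' only on proportions, so it is invariant to per-sample rescaling.
#'
#' @param table a [taxon_table] (any transform; typically filtered counts).
#' @return named numeric vector of H (nats), one per sample.
#' @export
shannon_index <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  totals <- rowSums(table$counts)
  if (any(totals <= 0)) {
    stop("sample(s) with non-positive total: ",
         paste(sample_ids(table)[totals <= 0], collapse = ", "))
  }
  vegan::diversity(table$counts, index = "shannon")
}

#' Tukey HSD compact letter display over groups
#'
#' One-way ANOVA followed by Tukey's honest significant difference test
#' (Tukey-Kramer on unbalanced groups, via [stats::TukeyHSD()]), then
#' compact letters assigned by the insert-and-absorb procedure: groups are
#' processed in descending mean order and two groups share a letter if and
#' only if their difference is not significant at `alpha`.
#'
#' @param values numeric response (e.g. per-sample Shannon H).
#' @param groups group labels, same length as `values`.
#' @param alpha significance level (default 0.05).
#' @return list with `letters` (data frame: `group`, `mean`, `n`,
#'   `letters`, ordered by descending mean) and `pairs` (the TukeyHSD
#'   pair table with adjusted p-values).
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  n_by <- table(groups)
  if (any(n_by < 2)) {
    stop("every group needs >= 2 samples; offending: ",
         paste(names(n_by)[n_by < 2], collapse = ", "))
  }
  fit <- stats::aov(values ~ groups)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- data.frame(pair = rownames(hsd), hsd, row.names = NULL)
  lv <- levels(groups)
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lv, lv))
  split_pair <- strsplit(rownames(hsd), "-", fixed = TRUE)
  for (i in seq_along(split_pair)) {
    a <- split_pair[[i]][1]; b <- split_pair[[i]][2]
    sig[a, b] <- sig[b, a] <- hsd[i, "p adj"] < alpha
  }
  means <- tapply(values, groups, mean)
  ord <- names(sort(means, decreasing = TRUE))
  letters_map <- cld_insert_absorb(sig[ord, ord, drop = FALSE])
  data_out <- data.frame(group = ord, mean = as.numeric(means[ord]),
                         n = as.integer(n_by[ord]),
                         letters = letters_map[ord],
                         stringsAsFactors = FALSE)
  list(letters = data_out, pairs = pairs)
}

# insert-and-absorb compact letter display from a pairwise significance
# matrix (TRUE = significantly different); rows/cols ordered as desired.
cld_insert_absorb <- function(sig) {
  g <- rownames(sig)
  cols <- list(g)  # start with one column holding all groups
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- g[pairs[r, 1]]; b <- g[pairs[r, 2]]
      new_cols <- list()
      for (cl in cols) {
        if (a %in% cl && b %in% cl) {
          new_cols <- c(new_cols, list(setdiff(cl, a)), list(setdiff(cl, b)))
        } else {
          new_cols <- c(new_cols, list(cl))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by first member's position, assign letters
  first_pos <- vapply(cols, function(cl) min(match(cl, g)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cols)) {
    for (m in cols[[i]]) out[m] <- paste0(out[m], letters[i])
  }
  out
}

#' Principal component scores of a log-normalized table
#'
#' Column-centred PCA (no scaling) of the log-transformed table; returns
#' the top `k` sample scores and the per-component fraction of variance
#' explained.
#'
#' @param table a [taxon_table] with `transform = "log_scaled"`, or a
#'   plain numeric matrix (samples x features).
#' @param k number of components to keep (default 10, capped at the rank).
#' @return list with `scores` (samples x k matrix), `variance_explained`
#'   (length-k fractions) and `total_variance_explained`.
#' @export
pca_scores <- function(table, k = 10) {
  x <- if (inherits(table, "taxon_table")) {
    if (table$transform != "log_scaled") {
      stop("pca_scores expects a log-normalized table, got ", table$transform)
    }
    table$counts
  } else as.matrix(table)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(p$x))
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)],
       total_variance_explained = sum(ve[seq_len(k)]))
}

#' 2-D sample embedding for beta diversity
#'
#' Embeds samples of a log-normalized table in two dimensions. Method
#' `"umap"` (default) delegates to the reference Python implementation of
#' uniform manifold approximation and projection (umap-learn) through a
#' subprocess, with a fixed `random_state` and seeded random
#' initialisation so the embedding is deterministic (spectral
#' initialisation is not reproducible when the neighbour graph is
#' disconnected, as it routinely is for strongly clustered communities);
#' method `"pca"` uses the first two principal components (always
#' available, fully in-process).
#'
#' @param table a log-scaled [taxon_table] or a numeric matrix with sample
#'   ids as row names.
#' @param method `"umap"` or `"pca"`.
#' @param seed random state for UMAP (default 42).
#' @param n_neighbors UMAP neighbourhood size (default 15; clamped to
#'   n-1 with a warning for small n).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param python path to the python interpreter (default `"python"`).
#' @return data frame with columns `dim1`, `dim2`, sample ids as row
#'   names; attributes `method` and `seed`.
#' @export
embed_samples <- function(table, method = c("umap", "pca"), seed = 42L,
                          n_neighbors = 15, min_dist = 0.1,
                          python = "python") {
  method <- match.arg(method)
  x <- if (inherits(table, "taxon_table")) {
    if (table$transform != "log_scaled") {
      stop("embed_samples expects a log-normalized table, got ",
           table$transform)
    }
    table$counts
  } else as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 samples to embed")
  if (method == "pca") {
    sc <- pca_scores(x, k = 2)$scores
    out <- data.frame(dim1 = sc[, 1], dim2 = sc[, 2], row.names = rownames(x))
  } else {
    if (Sys.which(python) == "") stop("python interpreter not found: ", python)
    n_neighbors <- as.integer(n_neighbors)
    if (n_neighbors >= nrow(x)) {
      n_neighbors <- nrow(x) - 1L
      warning("n_neighbors clamped to ", n_neighbors)
    }
    infile <- tempfile(fileext = ".tsv")
    outfile <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    utils::write.table(x, infile, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    code <- paste0(
      "import numpy as np, umap, warnings\n",
      "warnings.filterwarnings('ignore')\n",
      "X = np.loadtxt(r'", infile, "', delimiter='\\t', ndmin=2)\n",
      "emb = umap.UMAP(n_components=2, n_neighbors=", n_neighbors,
      ", min_dist=", min_dist, ", random_state=", as.integer(seed),
      ", init='random').fit_transform(X)\n",
      "np.savetxt(r'", outfile, "', emb, delimiter='\\t')\n")
    status <- system2(python, c("-c", shQuote(code)),
                      stdout = FALSE, stderr = "")
    if (status != 0 || !file.exists(outfile)) {
      stop("UMAP subprocess failed (exit status ", status, ")")
    }
    emb <- as.matrix(utils::read.delim(outfile, header = FALSE, sep = "\t"))
    out <- data.frame(dim1 = emb[, 1], dim2 = emb[, 2],
                      row.names = rownames(x))
  }
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  out
}

#' k-nearest-neighbour label purity of an embedding
#'
#' Fraction of samples whose majority label among the k nearest
#' neighbours matches their own label; a simple score for how cleanly an
#' ordination separates, e.g., cities.
#'
#' @param embedding 2-column coordinate matrix/data frame, sample ids as
#'   row names.
#' @param labels vector of labels aligned with the embedding rows.
#' @param k neighbourhood size (default 10).
#' @return a fraction in [0,1].
#' @export
knn_purity <- function(embedding, labels, k = 10) {
  coords <- as.matrix(embedding)
  stopifnot(nrow(coords) == length(labels), nrow(coords) >= 2)
  k <- min(k, nrow(coords) - 1)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  hits <- vapply(seq_len(nrow(coords)), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    tab <- table(labels[nn])
    names(tab)[which.max(tab)] == labels[i]
  }, logical(1))
  mean(hits)
}
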