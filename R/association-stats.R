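#' @importFrom stats aov TukeyHSD cor.test wilcox.test kruskal.test
#'   p.adjust hclust dist as.dendrogram order.dendrogram
NULL

#' Group sites into H/M/L mutagenesis levels
#'
#' One-way ANOVA of (normalized) editing frequency across the sites of one
#' multicopy family, followed by Tukey HSD pairwise tests at \code{alpha}.
#' Sites, sorted by descending mean, are swept into homogeneous subsets: a
#' site joins the current subset while it differs non-significantly from
#' every member; the first significant pair closes the subset. Subsets map
#' to labels by descending mean - 3 subsets give H/M/L; 2 give H/L; 1 gives
#' all-M; more than 3 label the first H, the last L, and all middle subsets
#' M.
#'
#' @param editing data.frame with columns \code{site} and \code{value}
#'   (one row per replicate; >= 3 sites with >= 2 replicates each).
#' @param alpha Tukey significance level (default 0.05).
#' @return data.frame with \code{site}, \code{mean}, \code{group} (H/M/L)
#'   ordered by descending mean; ANOVA p-value in attribute
#'   \code{"anova_p"}, subset index in column \code{subset}.
#' @export
assignGroups <- function(editing, alpha = 0.05) {
  editing$site <- as.character(editing$site)
  reps <- table(editing$site)
  if (length(reps) < 3) stop("need >= 3 sites to group")
  if (any(reps < 2))
    stop("need >= 2 replicates per site; short: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  fit <- aov(value ~ factor(site), data = editing)
  pAnova <- summary(fit)[[1]][["Pr(>F)"]][1]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
  pmat <- .tukeyPMatrix(tuk, names(reps))
  means <- sort(tapply(editing$value, editing$site, mean), decreasing = TRUE)
  ord <- names(means)
  subset <- integer(length(ord))
  cur <- 1L
  members <- ord[1]
  subset[1] <- cur
  for (i in seq_along(ord)[-1]) {
    s <- ord[i]
    if (all(pmat[members, s] >= alpha)) {
      members <- c(members, s)
    } else {
      cur <- cur + 1L
      members <- s
    }
    subset[i] <- cur
  }
  nSub <- max(subset)
  lab <- rep("M", nSub)
  if (nSub >= 2) {
    lab[1] <- "H"
    lab[nSub] <- "L"
  }
  data.frame(site = ord, mean = as.numeric(means), subset = subset,
             group = lab[subset], row.names = NULL) |>
    structure(anova_p = pAnova)
}

.tukeyPMatrix <- function(tuk, sites) {
  pmat <- matrix(1, length(sites), length(sites),
                 dimnames = list(sites, sites))
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    pmat[a, b] <- pmat[b, a] <- tuk[k, "p adj"]
  }
  pmat
}

#' Spearman correlation of chromatin features with an editing response
#'
#' Per feature: Spearman's rank correlation R (average ranks on ties) and
#' a two-sided P from the t approximation, plus Benjamini-Hochberg q-values
#' across features (the raw P is the primary report; the q column is
#' emitted for transparency). Constant feature or response gives an
#' undefined R, reported with \code{flag = "constant"}.
#'
#' @param features Numeric matrix or data.frame, observations x features.
#' @param response Numeric vector aligned with rows of \code{features}.
#' @param responseName Label for the response column ("efficiency" or
#'   "insertion_rate").
#' @return data.frame: \code{feature}, \code{response}, \code{n}, \code{R},
#'   \code{P}, \code{q}, \code{flag}.
#' @export
correlate <- function(features, response, responseName = "efficiency") {
  features <- as.matrix(features)
  if (nrow(features) != length(response))
    stop("features and response must be aligned")
  keep <- !is.na(response)
  features <- features[keep, , drop = FALSE]
  response <- response[keep]
  if (length(response) < 5) stop("need >= 5 observations")
  res <- lapply(colnames(features), function(f) {
    x <- features[, f]
    if (length(unique(x)) < 2 || length(unique(response)) < 2)
      return(data.frame(feature = f, response = responseName,
                        n = length(response), R = NA_real_, P = NA_real_,
                        flag = "constant"))
    ct <- suppressWarnings(
      cor.test(x, response, method = "spearman", exact = FALSE,
               alternative = "two.sided"))
    data.frame(feature = f, response = responseName, n = length(response),
               R = unname(ct$estimate), P = ct$p.value, flag = "")
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$P, method = "BH")
  out[, c("feature", "response", "n", "R", "P", "q", "flag")]
}

#' Hierarchically cluster features and sites of a normalized matrix
#'
#' Agglomerative clustering with average linkage on Euclidean distances,
#' for both the feature (column) and site (row) dimensions, on the
#' 0-1-normalized feature matrix. \code{hclust} resolves ties by input
#' order, so the layout is deterministic and reproducible.
#'
#' @param mat Numeric matrix, sites x features (normalized). Missing
#'   values are imputed with the column mean, with a warning.
#' @return list of class \code{ClusterLayout}: \code{featureHclust},
#'   \code{siteHclust} (\code{hclust} objects; NULL for a single
#'   feature/site), \code{featureOrder}, \code{siteOrder}, and
#'   \code{matrix} (reordered).
#' @export
clusterFeatures <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    warning("missing values imputed with column means")
    for (j in seq_len(ncol(mat))) {
      x <- mat[, j]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      mat[, j] <- x
    }
  }
  fh <- if (ncol(mat) > 1) hclust(dist(t(mat)), method = "average") else NULL
  sh <- if (nrow(mat) > 1) hclust(dist(mat), method = "average") else NULL
  fo <- if (is.null(fh)) 1L else fh$order
  so <- if (is.null(sh)) 1L else sh$order
  structure(list(featureHclust = fh, siteHclust = sh,
                 featureOrder = colnames(mat)[fo],
                 siteOrder = rownames(mat)[so],
                 matrix = mat[so, fo, drop = FALSE]),
            class = "ClusterLayout")
}

#' Compare editing between two conditions, per site
#'
#' Two-sided Mann-Whitney U test per site (exact for small samples without
#' ties, normal approximation with tie correction otherwise, as in
#' \code{stats::wilcox.test}), plus the fold change of condition means
#' mean(B)/mean(A). All-identical pooled values give P = 1.
#'
#' @param a,b data.frames with columns \code{site}, \code{value}
#'   (replicate-level) for conditions A and B; >= 3 replicates per
#'   condition per site.
#' @return data.frame: \code{site}, \code{n_a}, \code{n_b}, \code{U},
#'   \code{P}, \code{fold_change}.
#' @export
compareConditions <- function(a, b) {
  sites <- intersect(unique(a$site), unique(b$site))
  if (!length(sites)) stop("no shared sites between conditions")
  res <- lapply(sites, function(s) {
    va <- a$value[a$site == s]
    vb <- b$value[b$site == s]
    if (length(va) < 3 || length(vb) < 3)
      stop("need >= 3 replicates per condition at site ", s)
    if (length(unique(c(va, vb))) == 1) {
      p <- 1; u <- length(va) * length(vb) / 2
    } else {
      wt <- suppressWarnings(wilcox.test(va, vb, alternative = "two.sided"))
      p <- wt$p.value; u <- unname(wt$statistic)
    }
    data.frame(site = s, n_a = length(va), n_b = length(vb), U = u, P = p,
               fold_change = mean(vb) / mean(va))
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis test across families or groups
#'
#' Standard H statistic with tie correction and chi-square P (via
#' \code{stats::kruskal.test}).
#'
#' @param values Numeric vector of observations (e.g. insertion rates).
#' @param groups Factor/character of group membership, >= 2 groups with
#'   >= 2 observations each.
#' @return list: \code{H}, \code{df}, \code{P}.
#' @export
kruskalWallis <- function(values, groups) {
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("need >= 2 observations per group")
  kt <- kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter), P = kt$p.value)
}
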