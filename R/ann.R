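#' TSS chromatin-signature matrix
#'
#' Gene-by-feature matrix of promoter chromatin state: either the ten named
#' TSS windows of [tss_window_spec()] ("windows" mode) or, for each mark,
#' the bin score at 19 positions around the TSS (-450 to +450 bp in 50-bp
#' steps; 6 marks give 114 inputs, "positions" mode). Features are
#' z-standardized; zero-variance features are dropped with a warning.
#'
#' @param tracks Named list of `bin_track`s keyed by mark.
#' @param world A `synthetic_world`.
#' @param mode "windows" or "positions".
#' @param spec Window specification for "windows" mode.
#' @param positions Offsets (bp) for "positions" mode.
#' @return A `signature_matrix`: list with `x` (matrix, rownames gene ids),
#'   `center`, `scale`, `mode`.
#' @export
build_signature_matrix <- function(tracks, world,
                                   mode = c("windows", "positions"),
                                   spec = tss_window_spec(),
                                   positions = seq(-450, 450, by = 50)) {
  mode <- match.arg(mode)
  genes <- world$genes
  if (mode == "windows") {
    wide <- tss_window_means(tracks, world, spec)
    x <- as.matrix(wide[, -1, drop = FALSE])
    rownames(x) <- wide$gene_id
  } else {
    cols <- purrr::imap(tracks, function(tr, mark) {
      bin <- tr$bin
      layout <- track_layout(tr)
      sapply(positions, function(p) {
        dir <- ifelse(genes$strand == "+", 1L, -1L)
        gpos <- genes$tss + dir * p
        ok <- gpos >= 0 & gpos < layout[genes$chrom]
        v <- rep(NA_real_, nrow(genes))
        idx <- which(ok)
        b <- gpos[idx] %/% bin + 1L
        v[idx] <- vapply(seq_along(idx), function(r) {
          tr$scores[[genes$chrom[idx[r]]]][b[r]]
        }, numeric(1))
        v
      })
    })
    x <- do.call(cbind, cols)
    colnames(x) <- unlist(purrr::imap(tracks, function(tr, mark) {
      sprintf("%s_%+d", mark, positions)
    }))
    rownames(x) <- genes$gene_id
  }
  x[is.na(x)] <- 0
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warn(paste("dropping zero-variance feature(s):",
               paste(colnames(x)[zero], collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
    ctr <- ctr[!zero]; scl <- scl[!zero]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(x = z, center = ctr, scale = scl, mode = mode),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix>", nrow(x$x), "genes x", ncol(x$x),
      "features (", x$mode, ")\n")
  invisible(x)
}

#' Hierarchical clustering of TSS signatures
#'
#' Agglomerative clustering of genes by their chromatin signature
#' (correlation distance, average linkage by default), cut at `k`
#' clusters, with per-cluster expression summaries when expression is
#' supplied. Expression is displayed, not used in the metric.
#'
#' @param sig A [build_signature_matrix()] result (or bare matrix).
#' @param k Number of clusters (default 6).
#' @param distance "correlation" (1 - Pearson r between gene rows) or
#'   "euclidean".
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param expression Optional tibble `gene_id`, `expression`.
#' @return A `gene_clusters` list: `labels` tibble (`gene_id`, `cluster`),
#'   `hclust`, `k`, `summary` (per-cluster size and expression mean /
#'   quartiles when available).
#' @export
cluster_genes <- function(sig, k = 6L, distance = c("correlation", "euclidean"),
                          linkage = "average", expression = NULL) {
  distance <- match.arg(distance)
  x <- if (inherits(sig, "signature_matrix")) sig$x else sig
  if (k > nrow(x)) abort("k exceeds the number of genes")
  d <- if (distance == "correlation") {
    cc <- suppressWarnings(cor(t(x)))
    cc[!is.finite(cc)] <- 0
    as.dist(1 - cc)
  } else dist(x)
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = k)
  labels <- tibble(gene_id = rownames(x), cluster = unname(cl))
  summary <- labels %>% count(.data$cluster, name = "n_genes")
  if (!is.null(expression)) {
    summary <- labels %>%
      left_join(expression, by = "gene_id") %>%
      group_by(.data$cluster) %>%
      summarise(n_genes = n(),
                mean_expression = mean(.data$expression, na.rm = TRUE),
                q25 = quantile(.data$expression, 0.25, na.rm = TRUE),
                q75 = quantile(.data$expression, 0.75, na.rm = TRUE),
                .groups = "drop")
  }
  structure(list(labels = labels, hclust = hc, k = k, summary = summary),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat("<gene_clusters> k =", x$k, "\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy gene_clusters
#' @export
tidy.gene_clusters <- function(x, ...) x$labels

#' Linearly rescale expression to the 0-10 display scale
#'
#' @param expression Nonnegative expression values.
#' @return Values min-max rescaled to `[0, 10]`.
#' @export
scale_expression_0_10 <- function(expression) {
  rng <- range(expression, finite = TRUE)
  if (diff(rng) == 0) return(rep(0, length(expression)))
  10 * (expression - rng[1]) / (rng[2] - rng[1])
}

#' ANN configuration
#'
#' A four-layer feed-forward network: input layer, two hidden layers of 2
#' and 3 logistic-sigmoid neurons, and one linear output neuron estimating
#' quantitative expression on the 0-10 scale. Trained by BFGS on the mean
#' squared error with analytic gradients.
#'
#' @param hidden Hidden layer sizes (default `c(2, 3)`).
#' @param runs Independent training/evaluation runs (default 10).
#' @param train_fraction Fraction of genes in each run's random training
#'   split (default 0.5).
#' @param maxit BFGS iteration budget per run.
#' @param init_sd Standard deviation of the random weight initialization.
#' @param seed Base seed; run r uses `seed + r`.
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden = c(2L, 3L), runs = 10L, train_fraction = 0.5,
                       maxit = 600L, init_sd = 0.5, seed = 1L) {
  stopifnot(all(hidden >= 1), runs >= 1, train_fraction > 0,
            train_fraction < 1)
  structure(list(hidden = as.integer(hidden), runs = as.integer(runs),
                 train_fraction = train_fraction, maxit = as.integer(maxit),
                 init_sd = init_sd, seed = as.integer(seed)),
            class = "ann_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_sizes <- function(n_in, hidden) c(n_in, hidden, 1L)

mlp_n_par <- function(sizes) {
  sum((sizes[-length(sizes)] + 1) * sizes[-1])
}

mlp_unpack <- function(theta, sizes) {
  out <- vector("list", length(sizes) - 1)
  off <- 0
  for (l in seq_len(length(sizes) - 1)) {
    nw <- sizes[l] * sizes[l + 1]
    out[[l]] <- list(
      W = matrix(theta[off + seq_len(nw)], sizes[l], sizes[l + 1]),
      b = theta[off + nw + seq_len(sizes[l + 1])])
    off <- off + nw + sizes[l + 1]
  }
  out
}

mlp_forward <- function(layers, X) {
  a <- X
  acts <- list(a)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- a %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(a),
                                      length(layers[[l]]$b), byrow = TRUE)
    a <- if (l < nl) sigmoid(z) else z
    acts[[l + 1]] <- a
  }
  list(yhat = as.numeric(a), acts = acts)
}

# MSE loss and analytic gradient (backprop) as a flat parameter vector.
mlp_loss_grad <- function(theta, sizes, X, y) {
  layers <- mlp_unpack(theta, sizes)
  fw <- mlp_forward(layers, X)
  n <- length(y)
  err <- fw$yhat - y
  loss <- mean(err^2)
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- matrix(2 * err / n, ncol = 1)
  for (l in nl:1) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = t(a_prev) %*% delta, b = colSums(delta))
    if (l > 1) {
      a_l <- fw$acts[[l]]
      delta <- (delta %*% t(layers[[l]]$W)) * a_l * (1 - a_l)
    }
  }
  g <- unlist(lapply(grads, function(gr) c(as.numeric(gr$W), gr$b)))
  list(loss = loss, grad = g)
}

train_mlp_once <- function(X, y, hidden, maxit, init_sd) {
  sizes <- mlp_sizes(ncol(X), hidden)
  theta0 <- rnorm(mlp_n_par(sizes), sd = init_sd)
  fit <- optim(theta0,
               fn = function(th) mlp_loss_grad(th, sizes, X, y)$loss,
               gr = function(th) mlp_loss_grad(th, sizes, X, y)$grad,
               method = "BFGS", control = list(maxit = maxit))
  list(theta = fit$par, sizes = sizes, value = fit$value,
       layers = mlp_unpack(fit$par, sizes))
}

#' Train the expression-predicting network
#'
#' Per run: a seeded random half of the genes trains the network, the
#' held-out half is scored. Accuracy is `1 - mean(|predicted - true|) / 10`
#' on the 0-10 expression scale, reported alongside the Pearson r between
#' predicted and true values. Runs with a non-finite loss are restarted
#' with a fresh initialization (at most 3 restarts).
#'
#' @param sig A [build_signature_matrix()] (or bare matrix with gene
#'   rownames).
#' @param expression Tibble `gene_id`, `expression`; values are rescaled
#'   to 0-10 with [scale_expression_0_10()] unless already within `[0,10]`
#'   and `rescale = FALSE`.
#' @param config An [ann_config()].
#' @param rescale Rescale expression to 0-10 (default TRUE).
#' @return An `ann_result`: per-run tibble `runs` (accuracy, pearson_r),
#'   `importance` tibble (feature, mean, sd over runs), and the fitted
#'   models.
#' @export
train_ann <- function(sig, expression, config = ann_config(),
                      rescale = TRUE) {
  x <- if (inherits(sig, "signature_matrix")) sig$x else sig
  y_raw <- expression$expression[match(rownames(x), expression$gene_id)]
  if (any(is.na(y_raw))) abort("expression missing for some genes")
  y <- if (rescale) scale_expression_0_10(y_raw) else y_raw
  n <- nrow(x)
  runs <- vector("list", config$runs)
  models <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    fit <- withr::with_seed(config$seed + r, {
      tr_idx <- sample.int(n, round(config$train_fraction * n))
      attempt <- 0
      repeat {
        m <- train_mlp_once(x[tr_idx, , drop = FALSE], y[tr_idx],
                            config$hidden, config$maxit, config$init_sd)
        if (is.finite(m$value)) break
        attempt <- attempt + 1
        if (attempt > 3) abort("ANN training failed: non-finite loss after 3 restarts")
        inform("non-finite training loss; restarting with a new initialization")
      }
      m$test_idx <- setdiff(seq_len(n), tr_idx)
      m
    })
    pred <- mlp_forward(fit$layers, x[fit$test_idx, , drop = FALSE])$yhat
    truth <- y[fit$test_idx]
    runs[[r]] <- tibble(
      run = r,
      accuracy = 1 - mean(abs(pred - truth)) / 10,
      pearson_r = if (sd(pred) > 0) cor(pred, truth) else NA_real_)
    models[[r]] <- fit
  }
  imp <- vapply(models, function(m) garson_importance(m$layers),
                numeric(ncol(x)))
  importance <- tibble(
    feature = colnames(x),
    mean = rowMeans(imp),
    sd = apply(imp, 1, sd))
  structure(list(runs = bind_rows(runs), importance = importance,
                 models = models, config = config,
                 features = colnames(x)),
            class = "ann_result")
}

# Garson-style attribution: per input, total absolute weight over all
# input->output paths, normalized to sum 1.
garson_importance <- function(layers) {
  m <- abs(layers[[1]]$W)
  for (l in 2:length(layers)) m <- m %*% abs(layers[[l]]$W)
  v <- as.numeric(m)
  v / sum(v)
}

#' Input importance of a trained network
#'
#' Mean and standard deviation, over the independent runs, of the
#' Garson-style per-input importance (products of absolute weights along
#' all input-to-output paths, normalized to sum to 1).
#'
#' @param result An [train_ann()] result.
#' @return Tibble `feature`, `mean`, `sd`.
#' @export
ann_importance <- function(result) {
  stopifnot(inherits(result, "ann_result"))
  result$importance
}

#' @export
print.ann_result <- function(x, ...) {
  cat("<ann_result>", nrow(x$runs), "runs; mean accuracy",
      round(mean(x$runs$accuracy), 3), "; mean r",
      round(mean(x$runs$pearson_r), 3), "\n")
  invisible(x)
}

#' @method tidy ann_result
#' @export
tidy.ann_result <- function(x, ...) x$importance

#' @method glance ann_result
#' @export
glance.ann_result <- function(x, ...) {
  tibble(runs = nrow(x$runs),
         mean_accuracy = mean(x$runs$accuracy),
         sd_accuracy = sd(x$runs$accuracy),
         mean_pearson_r = mean(x$runs$pearson_r),
         top_feature = x$importance$feature[which.max(x$importance$mean)])
}
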