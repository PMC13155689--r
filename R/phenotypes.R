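#' Trade-off parameters
#'
#' Bundles the three constants that define the two physiological trade-offs:
#' the growth-death trade-off \eqn{\gamma = a e^{b\mu}} linking the growth
#' rate during feast to the death rate during famine, and the resource-use
#' trade-off fixing the geometric mean of each phenotype's growth rates
#' across nutrient environments at \eqn{\bar\mu}.
#'
#' @param a death-rate prefactor (1/time); death rate of a non-growing
#'   phenotype. Default 0.01.
#' @param b trade-off strength (time); how steeply the famine death rate
#'   rises with the feast growth rate. `b = 0` switches the trade-off off.
#'   Default 1.
#' @param mu_bar geometric-mean growth rate \eqn{\bar\mu} (1/time) shared by
#'   all phenotypes under the resource-use constraint.
#' @return An object of class `tradeoff_params`.
#' @examples
#' tradeoff_params(mu_bar = 0.4)
#' @export
tradeoff_params <- function(a = 0.01, b = 1, mu_bar) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b >= 0)
  stopifnot(is.numeric(mu_bar), length(mu_bar) == 1L, is.finite(mu_bar),
            mu_bar > 0)
  structure(list(a = a, b = b, mu_bar = mu_bar), class = "tradeoff_params")
}

#' @export
print.tradeoff_params <- function(x, ...) {
  cat(sprintf("Trade-off parameters: a = %g, b = %g, mu_bar = %g\n",
              x$a, x$b, x$mu_bar))
  invisible(x)
}

#' Death rate under the growth-death trade-off
#'
#' \eqn{\gamma = a \exp(b \mu)}: phenotypes that grow fast during feast die
#' fast during famine (exponential form, after starvation-survival
#' measurements in *E. coli*).
#'
#' @param mu growth rate(s) (1/time), non-negative.
#' @param params a [tradeoff_params()] object.
#' @return death rate(s) (1/time), same length as `mu`.
#' @examples
#' death_rate(0.8, tradeoff_params(a = 0.01, b = 1, mu_bar = 0.8))
#' @export
death_rate <- function(mu, params) {
  stopifnot(inherits(params, "tradeoff_params"))
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("growth rates must be finite and non-negative")
  }
  params$a * exp(params$b * mu)
}

## Internal constructor: assemble and validate a phenotype table.
## `adjacency` is an N x N logical/0-1 symmetric matrix with empty diagonal;
## storing it explicitly lets the chain (E = 2) and the simplex lattice
## (E = 3) share one switching-matrix code path.
new_phenotype_table <- function(mu, params, adjacency, labels,
                                coords = NULL) {
  mu <- as.matrix(mu)
  n <- nrow(mu)
  e <- ncol(mu)
  gamma <- params$a * exp(params$b * mu)
  adjacency <- (as.matrix(adjacency) != 0)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  diag(adjacency) <- FALSE
  if (any(mu <= 0)) stop("all growth rates must be positive")
  gm <- exp(rowMeans(log(mu)))
  if (any(abs(gm / params$mu_bar - 1) > 1e-10)) {
    stop("resource-use trade-off violated: geometric mean of growth rates ",
         "differs from mu_bar by more than 1e-10 (relative)")
  }
  structure(list(
    n_phenotypes = n, n_environments = e,
    mu = mu, gamma = gamma,
    adjacency = adjacency,
    labels = labels, coords = coords,
    params = params
  ), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf(
    "Phenotype table: %d phenotypes x %d environments (mu_bar = %g, a = %g, b = %g)\n",
    x$n_phenotypes, x$n_environments, x$params$mu_bar, x$params$a, x$params$b))
  cat("Labels:", paste(utils::head(x$labels, 6), collapse = ", "),
      if (x$n_phenotypes > 6) "..." else "", "\n")
  invisible(x)
}

#' Symmetric three-phenotype set (one generalist, two specialists)
#'
#' The minimal two-environment setup: phenotype 1 specializes in environment
#' A (\eqn{\mu_{1,A} = 2\bar\mu}, \eqn{\mu_{1,B} = \bar\mu/2}), phenotype 3
#' is its mirror image in environment B, and phenotype 2 is the generalist
#' with \eqn{\mu_{2,A} = \mu_{2,B} = \bar\mu}. Each row satisfies the
#' geometric-mean constraint; adjacency is the chain 1-2-3 so switching
#' passes through the generalist.
#'
#' @param params a [tradeoff_params()] object.
#' @return A `phenotype_table`.
#' @examples
#' build_three_phenotype_set(tradeoff_params(mu_bar = 0.4))
#' @export
build_three_phenotype_set <- function(params) {
  stopifnot(inherits(params, "tradeoff_params"))
  mb <- params$mu_bar
  mu <- rbind(c(2 * mb, mb / 2),
              c(mb,     mb),
              c(mb / 2, 2 * mb))
  colnames(mu) <- c("A", "B")
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  new_phenotype_table(mu, params, adj,
                      labels = c("specialist_A", "generalist", "specialist_B"))
}

#' Quasi-continuous phenotype ladder (two environments)
#'
#' A geometric ladder of N phenotypes, \eqn{\mu_{i,A} = \bar\mu g_i},
#' \eqn{\mu_{i,B} = \bar\mu / g_i} with \eqn{g_i = g(0) m^{c i}} and
#' \eqn{g(0) = m^{-c(N+1)/2}}, so the central phenotype \eqn{i = (N+1)/2}
#' has \eqn{g = 1} and is the generalist. Adjacency is the chain
#' \eqn{i \leftrightarrow i+1}.
#'
#' @param params a [tradeoff_params()] object.
#' @param n number of phenotypes; must be odd so a central generalist exists.
#' @param m ladder base (> 1). Default 2.
#' @param c_step ladder exponent spacing (> 0). Default 0.2.
#' @return A `phenotype_table`. The component `coords` holds the ladder
#'   exponents \eqn{\log_m g_i / c} (signed distance from the generalist).
#' @examples
#' build_ladder_set(tradeoff_params(mu_bar = 0.5), n = 51)
#' @export
build_ladder_set <- function(params, n = 51, m = 2, c_step = 0.2) {
  stopifnot(inherits(params, "tradeoff_params"))
  stopifnot(length(n) == 1L, n >= 3)
  if (n %% 2 == 0) stop("n must be odd so a symmetric central generalist exists")
  stopifnot(m > 1, c_step > 0)
  i <- seq_len(n)
  g <- m^(c_step * (i - (n + 1) / 2))  # g(0) = m^(-c(n+1)/2) folded in
  mu <- cbind(A = params$mu_bar * g, B = params$mu_bar / g)
  center <- (n + 1) / 2
  stopifnot(abs(mu[center, 1] - mu[center, 2]) < 1e-12 * params$mu_bar)
  adj <- matrix(FALSE, n, n)
  idx <- cbind(i[-n], i[-n] + 1L)
  adj[idx] <- TRUE
  adj[idx[, 2:1, drop = FALSE]] <- TRUE
  labels <- sprintf("ladder_%02d", i)
  labels[center] <- "generalist"
  new_phenotype_table(mu, params, adj, labels = labels,
                      coords = i - center)
}

#' Simplex lattice of phenotypes for three environments
#'
#' Phenotypes live on the integer lattice
#' \eqn{(x, y, z) = s (k_1, k_2, k_3)} with \eqn{k_1 + k_2 + k_3 = 0} and
#' \eqn{|k_j| \le} `extent`; growth rates are
#' \eqn{(\bar\mu 2^x, \bar\mu 2^y, \bar\mu 2^z)}, so the zero-sum constraint
#' enforces the geometric-mean trade-off exactly. Neighbors differ by
#' \eqn{+s} in one coordinate and \eqn{-s} in another with the third held
#' fixed; interior nodes therefore have six neighbors.
#'
#' @param params a [tradeoff_params()] object.
#' @param step exponent increment \eqn{s} (> 0). Default 0.2.
#' @param extent lattice radius (max \eqn{|k_j|}), an integer \eqn{\ge 1}.
#'   Default 5.
#' @return A `phenotype_table`; `coords` is the K x 3 matrix of integer
#'   lattice indices \eqn{(k_1, k_2, k_3)}.
#' @examples
#' tab <- build_simplex_set(tradeoff_params(mu_bar = 0.6), extent = 2)
#' tab$n_phenotypes
#' @export
build_simplex_set <- function(params, step = 0.2, extent = 5) {
  stopifnot(inherits(params, "tradeoff_params"))
  stopifnot(step > 0, extent >= 1, extent == round(extent))
  ks <- expand.grid(k1 = -extent:extent, k2 = -extent:extent)
  ks$k3 <- -(ks$k1 + ks$k2)
  ks <- ks[abs(ks$k3) <= extent, , drop = FALSE]
  ks <- as.matrix(ks[order(ks$k1, ks$k2), , drop = FALSE])
  rownames(ks) <- NULL
  n <- nrow(ks)
  xyz <- step * ks
  mu <- params$mu_bar * 2^xyz
  colnames(mu) <- c("A", "B", "C")
  # neighbors: +1 in one k, -1 in another, third fixed
  adj <- matrix(FALSE, n, n)
  key <- ks %*% c(1, (2L * extent + 1L), (2L * extent + 1L)^2)
  moves <- rbind(c(1, -1, 0), c(-1, 1, 0), c(1, 0, -1),
                 c(-1, 0, 1), c(0, 1, -1), c(0, -1, 1))
  for (mv in seq_len(nrow(moves))) {
    tgt <- ks + matrix(moves[mv, ], n, 3, byrow = TRUE)
    ok <- apply(abs(tgt) <= extent, 1, all)
    tkey <- tgt %*% c(1, (2L * extent + 1L), (2L * extent + 1L)^2)
    j <- match(tkey, key)
    hit <- ok & !is.na(j)
    adj[cbind(which(hit), j[hit])] <- TRUE
  }
  labels <- sprintf("simplex_%+d%+d%+d", ks[, 1], ks[, 2], ks[, 3])
  labels[rowSums(abs(ks)) == 0] <- "generalist"
  new_phenotype_table(mu, params, adj, labels = labels, coords = ks)
}

#' Phenotype switching matrix
#'
#' Per-division probability that a daughter cell adopts a neighboring
#' phenotype: \eqn{A_{ij} = p} when phenotypes i and j are adjacent in the
#' table's strategy space, 0 otherwise (diagonal 0).
#'
#' @param table a `phenotype_table`.
#' @param p switching probability per division, \eqn{0 \le p}; the total
#'   outflow \eqn{p \times} (neighbor count) must stay below 1.
#' @return N x N numeric matrix of switching probabilities.
#' @examples
#' switching_matrix(build_three_phenotype_set(tradeoff_params(mu_bar = 0.4)),
#'                  p = 1e-4)
#' @export
switching_matrix <- function(table, p = 1e-4) {
  stopifnot(inherits(table, "phenotype_table"))
  stopifnot(length(p) == 1L, is.finite(p), p >= 0)
  A <- table$adjacency * p
  if (any(rowSums(A) >= 1)) {
    stop("switching probability too large: a row sum of the switching ",
         "matrix reaches 1")
  }
  A
}

#' Growth-to-death ratio of each phenotype
#'
#' The dominance statistic \eqn{r_i = \langle\mu_i\rangle /
#' \langle\gamma_i\rangle}, where the brackets are arithmetic means over
#' nutrient environments. The phenotype with the largest r dominates the
#' population at steady state; for more than two environments the mean is
#' taken over all of them.
#'
#' @param table a `phenotype_table`.
#' @return named numeric vector of ratios, one per phenotype.
#' @examples
#' growth_death_ratio(build_three_phenotype_set(tradeoff_params(mu_bar = 0.8)))
#' @export
growth_death_ratio <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  r <- rowMeans(table$mu) / rowMeans(table$gamma)
  names(r) <- table$labels
  r
}

#' Write / read a phenotype table as CSV
#'
#' One row per phenotype: id, label, per-environment growth and death rates
#' and a semicolon-separated neighbor list, so experiment configurations can
#' pin exact phenotype spaces. `read_phenotype_table()` reconstructs the
#' table and re-validates both trade-offs.
#'
#' @param table a `phenotype_table`.
#' @param path file path.
#' @return `write_phenotype_table()` returns `path` invisibly;
#'   `read_phenotype_table()` returns a `phenotype_table`.
#' @export
write_phenotype_table <- function(table, path) {
  stopifnot(inherits(table, "phenotype_table"))
  env_names <- colnames(table$mu)
  if (is.null(env_names)) env_names <- as.character(seq_len(table$n_environments))
  df <- data.frame(id = seq_len(table$n_phenotypes), label = table$labels)
  for (e in seq_len(table$n_environments)) {
    df[[paste0("mu_", env_names[e])]] <- table$mu[, e]
    df[[paste0("gamma_", env_names[e])]] <- table$gamma[, e]
  }
  df$neighbors <- vapply(seq_len(table$n_phenotypes), function(i) {
    paste(which(table$adjacency[i, ]), collapse = ";")
  }, character(1))
  hdr <- sprintf("# a=%.17g b=%.17g mu_bar=%.17g",
                 table$params$a, table$params$b, table$params$mu_bar)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  hdr <- readLines(path, n = 1)
  vals <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  params <- tradeoff_params(a = vals[1], b = vals[2], mu_bar = vals[3])
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  mu_cols <- grep("^mu_", names(df))
  mu <- as.matrix(df[, mu_cols, drop = FALSE])
  colnames(mu) <- sub("^mu_", "", names(df)[mu_cols])
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- df$neighbors[i]
    if (!is.na(nb) && nzchar(nb)) {
      adj[i, as.integer(strsplit(nb, ";")[[1]])] <- TRUE
    }
  }
  new_phenotype_table(mu, params, adj, labels = df$label)
}
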