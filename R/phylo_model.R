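## Continuous-time Markov substitution model, pruning likelihoods, and
## marginal maximum-likelihood ancestral state reconstruction.

#' Construct a reversible substitution model
#'
#' Builds the normalized rate matrix `Q[i,j] = S[i,j] * pi[j]` (i != j) from
#' a symmetric exchangeability matrix and stationary frequencies, scaled so
#' that the expected substitution rate at stationarity is one
#' (`-sum(pi_i Q_ii) = 1`), i.e. branch lengths are in expected
#' substitutions per site. Transition matrices are obtained by symmetric
#' eigendecomposition of the pi-rescaled generator, so `P(t) = exp(Qt)` is
#' computed stably for any `t >= 0`.
#'
#' @param exchangeabilities symmetric matrix with non-negative off-diagonal
#'   entries (diagonal ignored).
#' @param frequencies positive stationary frequencies summing to one.
#' @param states state labels (defaults to the 20 amino acids); the matrix
#'   dimension must match.
#' @param name model name recorded for run metadata.
#' @param gamma_shape optional shape of a discrete-gamma rate model.
#' @param gamma_categories number of discrete rate categories when
#'   `gamma_shape` is set.
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(exchangeabilities, frequencies,
                               states = AA_STATES, name = "custom",
                               gamma_shape = NULL, gamma_categories = 4L) {
  S <- as.matrix(exchangeabilities)
  k <- length(states)
  if (!all(dim(S) == c(k, k)))
    stop("validation error: exchangeability matrix dimension does not match states")
  if (max(abs(S - t(S))) > 1e-8)
    stop("validation error: exchangeability matrix is not symmetric")
  offdiag <- S[row(S) != col(S)]
  if (any(offdiag < 0))
    stop("validation error: negative exchangeability")
  pi <- as.numeric(frequencies)
  if (length(pi) != k || any(pi <= 0))
    stop("validation error: frequencies must be positive and match states")
  if (abs(sum(pi) - 1) > 1e-6)
    stop("validation error: frequencies do not sum to 1")
  pi <- pi / sum(pi)

  Q <- S * rep(pi, each = k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("validation error: degenerate rate matrix")
  Q <- Q / mu

  ## symmetric form B = D^{1/2} Q D^{-1/2}; eigendecompose once
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  left <- eig$vectors / d          # D^{-1/2} U
  right <- t(eig$vectors * d)      # U' D^{1/2}

  rates <- 1
  rate_weights <- 1
  if (!is.null(gamma_shape)) {
    rates <- discrete_gamma_rates(gamma_shape, gamma_categories)
    rate_weights <- rep(1 / gamma_categories, gamma_categories)
  }

  m <- structure(list(
    states = states, S = S, pi = pi, Q = Q,
    eigen_values = eig$values, eigen_left = left, eigen_right = right,
    name = name, gamma_shape = gamma_shape,
    rates = rates, rate_weights = rate_weights
  ), class = "substitution_model")
  validate_model(m)
  m
}

validate_model <- function(m) {
  if (abs(sum(m$pi) - 1) > 1e-12)
    stop("validation error: frequencies do not sum to 1")
  if (max(abs(rowSums(m$Q))) > 1e-10)
    stop("validation error: rate-matrix rows do not sum to 0")
  if (abs(-sum(m$pi * diag(m$Q)) - 1) > 1e-10)
    stop("validation error: rate matrix not normalized to one substitution/site")
  invisible(m)
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model '", x$name, "': ", length(x$states), " states",
      if (!is.null(x$gamma_shape))
        sprintf(", gamma(%g) x %d rates", x$gamma_shape, length(x$rates)),
      "\n", sep = "")
  invisible(x)
}

#' Discrete-gamma rate categories (mean one)
#'
#' Median-of-bin discretization of a Gamma(shape, shape) distribution into
#' `k` equiprobable categories, renormalized to mean one.
#' @param shape gamma shape (alpha).
#' @param k number of categories.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = shape, rate = shape)
  r / mean(r)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Entries more negative than `-1e-12` raise an error; smaller negative
#' round-off is clipped to zero and rows renormalized.
#' @param model a `substitution_model`.
#' @param t branch length (>= 0, expected substitutions/site).
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- model$eigen_left %*% (exp(model$eigen_values * t) * model$eigen_right)
  if (any(P < -1e-12))
    stop("transition matrix entry below tolerance at t = ", t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Parse a PAML-format empirical amino-acid matrix file
#'
#' Reads the lower-triangle exchangeabilities (19 rows) followed by the 20
#' stationary frequencies; tokens beyond these are ignored, so trailing
#' comments are tolerated.
#' @param path a `.dat` file.
#' @return list with `S` (symmetric 20x20) and `pi`.
#' @export
parse_paml_dat <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  num <- suppressWarnings(as.numeric(toks))
  num <- num[is.finite(num)]
  if (length(num) < 210)
    stop("validation error: expected at least 210 numbers in ", path)
  S <- matrix(0, 20, 20)
  idx <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- num[idx]; S[j, i] <- num[idx]
    idx <- idx + 1L
  }
  pi <- num[idx:(idx + 19L)]
  list(S = S, pi = pi)
}

#' Load an empirical substitution model
#'
#' `name_or_path` may be one of the shipped matrices (`"LG"`, `"WAG"`,
#' `"JTT"`) or a path to a PAML-format `.dat` file. Supplying `frequencies`
#' (a numeric vector, or an [msa()] from which empirical "+F" frequencies
#' are counted) overrides the matrix's own frequencies.
#'
#' @param name_or_path model name or `.dat` path.
#' @param frequencies optional override (numeric length-20, or an `msa`).
#' @param gamma_shape,gamma_categories optional discrete-gamma rate model.
#' @return a `substitution_model`.
#' @export
load_model <- function(name_or_path = "LG", frequencies = NULL,
                       gamma_shape = NULL, gamma_categories = 4L) {
  shipped <- c(LG = "lg.dat", WAG = "wag.dat", JTT = "jtt.dat")
  key <- toupper(name_or_path)
  if (key %in% names(shipped)) {
    path <- system.file("extdata", "models", shipped[[key]],
                        package = "convscan", mustWork = TRUE)
    name <- key
  } else {
    path <- name_or_path
    if (!file.exists(path)) stop("no shipped model or file named ", name_or_path)
    name <- tools::file_path_sans_ext(basename(path))
  }
  dat <- parse_paml_dat(path)
  pi <- dat$pi
  if (!is.null(frequencies)) {
    pi <- if (inherits(frequencies, "msa")) empirical_frequencies(frequencies)
          else as.numeric(frequencies)
    name <- paste0(name, "+F")
  }
  substitution_model(dat$S, pi, states = AA_STATES, name = name,
                     gamma_shape = gamma_shape,
                     gamma_categories = gamma_categories)
}

#' Empirical amino-acid frequencies of an alignment ("+F")
#'
#' Counts residues over `states` with a pseudocount so every frequency is
#' strictly positive.
#' @param x an [msa()].
#' @param states state labels.
#' @param pseudocount added to each state count.
#' @export
empirical_frequencies <- function(x, states = AA_STATES, pseudocount = 1) {
  stopifnot(inherits(x, "msa"))
  counts <- table(factor(x$mat[x$mat %in% states], levels = states))
  f <- as.numeric(counts) + pseudocount
  f / sum(f)
}

## ---------------------------------------------------------------------------
## Pruning
## ---------------------------------------------------------------------------

## Tip partial-likelihood matrix (k states x n sites) for one leaf row.
tip_partials <- function(residues, states) {
  k <- length(states)
  out <- matrix(0, k, length(residues))
  miss <- is_missing_residue(residues)
  out[, miss] <- 1
  obs <- which(!miss)
  if (length(obs)) {
    si <- match(residues[obs], states)
    if (anyNA(si))
      stop("residue outside model alphabet: ",
           paste(unique(residues[obs][is.na(si)]), collapse = ", "))
    out[cbind(si, obs)] <- 1
  }
  out
}

## Down (inside) pass for one rate category. Returns per-node partials
## (scaled columnwise) and per-site log scaling factors accumulated to each
## node, plus cached child transition matrices.
prune_down <- function(tree, mat, model, rate = 1, scale = 1) {
  states <- model$states
  k <- length(states)
  S <- ncol(mat)
  n_all <- tree$n_tip + tree$n_node
  partial <- vector("list", n_all)
  logs <- matrix(0, n_all, max(S, 1L))
  Pmat <- vector("list", n_all)
  for (tip in seq_len(tree$n_tip))
    partial[[tip]] <- tip_partials(mat[tree$tip_labels[tip], ], states)
  for (v in postorder_nodes(tree)) {
    if (v <= tree$n_tip) next
    M <- matrix(1, k, S)
    lg <- rep(0, S)
    for (ch in tree$children[[v]]) {
      P <- transition_matrix(model, rate * scale * tree$edge_length[ch])
      Pmat[[ch]] <- P
      M <- M * (P %*% partial[[ch]])
      lg <- lg + logs[ch, seq_len(S)]
    }
    cmax <- apply(M, 2L, max)
    cmax[cmax == 0] <- 1
    M <- sweep(M, 2L, cmax, "/")
    partial[[v]] <- M
    logs[v, seq_len(S)] <- lg + log(cmax)
  }
  list(partial = partial, logs = logs, P = Pmat)
}

## Per-site log-likelihood for one rate category from a down pass.
root_loglik <- function(tree, down, model) {
  S <- ncol(down$partial[[tree$root]])
  L <- colSums(model$pi * down$partial[[tree$root]])
  log(L) + down$logs[tree$root, seq_len(S)]
}

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Felsenstein pruning over all columns; with a discrete-gamma model the
#' site likelihood is the mean over rate categories. Gaps, `X` and `*` at
#' tips are uninformative (partial vector of ones).
#'
#' @param tree a `phylo_tree` containing every alignment row as a tip.
#' @param x an [msa()].
#' @param model a `substitution_model`.
#' @param scale global multiplier applied to all branch lengths.
#' @return numeric vector of per-site log-likelihoods.
#' @export
site_logliks <- function(tree, x, model, scale = 1) {
  stopifnot(inherits(tree, "phylo_tree"), inherits(x, "msa"))
  missing <- setdiff(x$ids, tree$tip_labels)
  if (length(missing))
    stop("alignment rows missing from tree: ", paste(missing, collapse = ", "))
  mat <- x$mat
  ncat <- length(model$rates)
  ll_cat <- matrix(0, ncat, ncol(mat))
  for (c in seq_len(ncat)) {
    down <- prune_down(tree, mat, model, rate = model$rates[c], scale = scale)
    ll_cat[c, ] <- root_loglik(tree, down, model)
  }
  if (ncat == 1L) return(ll_cat[1L, ])
  w <- model$rate_weights
  mx <- apply(ll_cat, 2L, max)
  mx + log(colSums(w * exp(sweep(ll_cat, 2L, mx, "-"))))
}

#' Likelihood of a single site pattern
#'
#' @param tree a `phylo_tree`.
#' @param column named character vector of tip residues (leaf label ->
#'   residue); gaps and `X` are missing data.
#' @param model a `substitution_model`.
#' @return the site likelihood (a probability density over patterns).
#' @export
site_likelihood <- function(tree, column, model) {
  stopifnot(!is.null(names(column)))
  x <- msa(names(column), unname(column))
  exp(site_logliks(tree, x, model))
}

#' Total log-likelihood of an alignment
#' @inheritParams site_logliks
#' @export
tree_loglik <- function(tree, x, model, scale = 1)
  sum(site_logliks(tree, x, model, scale = scale))

## ---------------------------------------------------------------------------
## Marginal ancestral state reconstruction
## ---------------------------------------------------------------------------

#' Marginal maximum-likelihood ancestral state reconstruction
#'
#' Computes, for every internal node and site, the posterior distribution of
#' the ancestral state given all tip data and the model, via inside-outside
#' (down + up) passes of the pruning algorithm. MAP states are recorded with
#' their posterior; ties (posterior within `tie_tol` of the maximum for more
#' than one state) are flagged and broken lexicographically by one-letter
#' code. With a discrete-gamma model, per-category posteriors are mixed with
#' weights proportional to the per-category site likelihood.
#'
#' @param tree a `phylo_tree` with at least one internal node.
#' @param x an [msa()] whose rows are all tips of `tree`.
#' @param model a `substitution_model`.
#' @param scale global branch-length multiplier.
#' @param tie_tol posterior difference below which two states tie.
#' @return an object of class `asr_table`: posteriors (list of
#'   states-x-sites matrices per internal node), `map`, `map_posterior` and
#'   `tie` matrices (internal nodes x sites), site coordinates, and state
#'   labels.
#' @export
marginal_asr <- function(tree, x, model, scale = 1, tie_tol = 1e-9) {
  stopifnot(inherits(tree, "phylo_tree"), inherits(x, "msa"))
  if (tree$n_node < 1L) stop("tree has no internal node")
  missing <- setdiff(x$ids, tree$tip_labels)
  if (length(missing))
    stop("alignment rows missing from tree: ", paste(missing, collapse = ", "))
  states <- model$states
  k <- length(states)
  S <- ncol(x$mat)
  internals <- (tree$n_tip + 1L):(tree$n_tip + tree$n_node)
  ncat <- length(model$rates)

  post_cat <- vector("list", ncat)
  ll_cat <- matrix(0, ncat, S)
  for (cat in seq_len(ncat)) {
    down <- prune_down(tree, x$mat, model, rate = model$rates[cat], scale = scale)
    ll_cat[cat, ] <- root_loglik(tree, down, model)
    up <- vector("list", tree$n_tip + tree$n_node)
    up[[tree$root]] <- matrix(model$pi, k, S)
    for (u in preorder_nodes(tree)) {
      if (u <= tree$n_tip) next
      kids <- tree$children[[u]]
      downs <- lapply(kids, function(ch) down$P[[ch]] %*% down$partial[[ch]])
      for (i in seq_along(kids)) {
        v <- kids[i]
        if (v <= tree$n_tip) next
        U <- up[[u]]
        for (j in seq_along(kids)) if (j != i) U <- U * downs[[j]]
        Uv <- crossprod(down$P[[v]], U)
        cmax <- apply(Uv, 2L, max)
        cmax[cmax == 0] <- 1
        up[[v]] <- sweep(Uv, 2L, cmax, "/")
      }
    }
    pc <- vector("list", length(internals))
    names(pc) <- as.character(internals)
    for (v in internals) {
      raw <- up[[v]] * down$partial[[v]]
      tot <- colSums(raw)
      tot[tot == 0] <- 1
      pc[[as.character(v)]] <- sweep(raw, 2L, tot, "/")
    }
    post_cat[[cat]] <- pc
  }

  if (ncat == 1L) {
    posterior <- post_cat[[1L]]
  } else {
    w <- model$rate_weights
    mx <- apply(ll_cat, 2L, max)
    wsite <- sweep(exp(sweep(ll_cat, 2L, mx, "-")) * w, 2L,
                   colSums(exp(sweep(ll_cat, 2L, mx, "-")) * w), "/")
    posterior <- vector("list", length(internals))
    names(posterior) <- as.character(internals)
    for (v in as.character(internals)) {
      acc <- matrix(0, k, S)
      for (cat in seq_len(ncat))
        acc <- acc + sweep(post_cat[[cat]][[v]], 2L, wsite[cat, ], "*")
      posterior[[v]] <- acc
    }
  }

  map <- matrix("", length(internals), S,
                dimnames = list(as.character(internals), NULL))
  map_post <- matrix(0, length(internals), S,
                     dimnames = list(as.character(internals), NULL))
  tie <- matrix(FALSE, length(internals), S,
                dimnames = list(as.character(internals), NULL))
  for (v in as.character(internals)) {
    pv <- posterior[[v]]
    rownames(pv) <- states
    mx <- apply(pv, 2L, max)
    for (s in seq_len(S)) {
      top <- which(pv[, s] >= mx[s] - tie_tol)
      map[v, s] <- states[top[order(states[top])][1L]]
      map_post[v, s] <- mx[s]
      tie[v, s] <- length(top) > 1L
    }
    posterior[[v]] <- pv
  }

  structure(list(
    posterior = posterior, map = map, map_posterior = map_post, tie = tie,
    nodes = internals, states = states, sites = x$column_map,
    loglik = if (ncat == 1L) ll_cat[1L, ] else NULL
  ), class = "asr_table")
}

#' @export
print.asr_table <- function(x, ...) {
  cat("asr_table: ", length(x$nodes), " internal nodes x ",
      ncol(x$map), " sites\n", sep = "")
  invisible(x)
}

#' Write an ASR table as TSV (node, site, MAP, posterior, tie)
#' @param asr an `asr_table`.
#' @param path output file.
#' @export
write_asr_table <- function(asr, path) {
  S <- ncol(asr$map)
  df <- data.frame(
    node = rep(asr$nodes, each = S),
    site = rep(asr$sites, times = length(asr$nodes)),
    map = as.vector(t(asr$map)),
    posterior = as.vector(t(asr$map_posterior)),
    tie = as.vector(t(asr$tie)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a global branch-length scale factor
#'
#' One-dimensional maximum-likelihood fit of a multiplier `c` applied to all
#' branch lengths, for user trees whose lengths may not be in substitutions
#' per site. For an alignment with no variable site the likelihood is flat
#' in `c` up to saturation; the function returns 1 with a warning.
#'
#' @param tree a `phylo_tree`.
#' @param x an [msa()] with at least two rows.
#' @param model a `substitution_model`.
#' @param interval search interval for `c`.
#' @return the fitted scale (never worse, in log-likelihood, than `c = 1`).
#' @export
fit_branch_scale <- function(tree, x, model, interval = c(1e-3, 1e3)) {
  stopifnot(inherits(x, "msa"), nrow(x$mat) >= 2L)
  variable <- apply(x$mat, 2L, function(col) {
    r <- unique(col[!is_missing_residue(col)])
    length(r) > 1L
  })
  if (!any(variable)) {
    warning("all-constant alignment: branch scale not identifiable, returning 1")
    return(1)
  }
  f <- function(logc) tree_loglik(tree, x, model, scale = exp(logc))
  opt <- stats::optimize(f, interval = log(interval), maximum = TRUE, tol = 1e-6)
  chat <- exp(opt$maximum)
  if (opt$objective < f(0)) return(1)
  chat
}
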