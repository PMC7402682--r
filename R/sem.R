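#' Directed acyclic graph for a piecewise SEM
#'
#' @param edges Data frame with columns `from`, `to`, one row per directed
#'   edge, or a character vector of `"from -> to"` strings.
#' @param exogenous Character vector of exogenous nodes (covariates whose
#'   mutual (in)dependence the model makes no claim about).
#' @return An object of class `sem_dag`: nodes in topological order, edges,
#'   exogenous set, and a parent list.
#' @export
sem_dag <- function(edges, exogenous = character()) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    edges <- tibble::tibble(from = trimws(vapply(parts, `[`, "", 1)),
                            to = trimws(vapply(parts, `[`, "", 2)))
  }
  edges <- tibble::as_tibble(edges)[c("from", "to")]
  nodes <- unique(c(edges$from, edges$to, exogenous))
  parents <- lapply(setNames(nodes, nodes),
                    function(nd) edges$from[edges$to == nd])
  # Kahn topological sort; fails on cycles
  order <- character()
  remaining <- nodes
  deps <- parents
  while (length(remaining)) {
    free <- remaining[vapply(remaining,
                             function(nd) !length(intersect(deps[[nd]],
                                                            remaining)),
                             logical(1))]
    if (!length(free)) abort("Graph is cyclic.", class = "befmeta_cyclic")
    order <- c(order, sort(free))
    remaining <- setdiff(remaining, free)
  }
  if (length(bad <- setdiff(exogenous, nodes[!nodes %in% edges$to]))) {
    abort(sprintf("Exogenous node(s) with incoming edges: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(nodes = order, edges = edges, exogenous = exogenous,
                 parents = parents), class = "sem_dag")
}

#' Standard decomposition-mediation graph
#'
#' The piecewise SEM used for one driver-by-response dataset: driver
#' intensity, study type and taxonomic group (plus diversity metric for
#' diversity datasets) predict the biodiversity response `zB`; `zB`, intensity
#' and study type predict the decomposition response `zLD`.  The reduced graph
#' used by the mediation test omits the `zB -> zLD` edge.
#'
#' @param kind `"diversity"` or `"abundance"` (controls the diversity-metric
#'   covariate).
#' @param biodiversity_path Include the `zB -> zLD` edge (default TRUE).
#' @return A [sem_dag()].
#' @export
mediation_dag <- function(kind = c("diversity", "abundance"),
                          biodiversity_path = TRUE) {
  kind <- match.arg(kind)
  edges <- c("intensity -> zB", "study_type -> zB", "taxon_group -> zB",
             if (kind == "diversity") "diversity_metric -> zB",
             if (biodiversity_path) "zB -> zLD",
             "intensity -> zLD", "study_type -> zLD")
  exo <- c("intensity", "study_type", "taxon_group",
           if (kind == "diversity") "diversity_metric")
  sem_dag(edges, exogenous = exo)
}

#' d-separation basis set of a DAG
#'
#' Enumerates the conditional-independence claims implied by the missing
#' edges of the graph: one claim per non-adjacent pair of nodes, excluding
#' pairs where both nodes are exogenous.  Each claim conditions on the union
#' of both nodes' parents, and is oriented so that `y` is the endogenous node
#' that comes later in topological order (the node in whose regression the
#' claim is tested).
#'
#' @param dag A [sem_dag()].
#' @return A tibble with columns `x`, `y`, and list-column `conditioning`.
#' @export
basis_set <- function(dag) {
  stopifnot(inherits(dag, "sem_dag"))
  nodes <- dag$nodes
  adj <- paste(dag$edges$from, dag$edges$to)
  claims <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        a <- nodes[i]; b <- nodes[j]  # topological order: a before b
        if (a %in% dag$exogenous && b %in% dag$exogenous) next
        if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
        y <- if (b %in% dag$exogenous) a else b
        x <- if (y == b) a else b
        cond <- setdiff(union(dag$parents[[x]], dag$parents[[y]]), c(x, y))
        claims[[length(claims) + 1L]] <-
          tibble::tibble(x = x, y = y, conditioning = list(sort(cond)))
      }
    }
  }
  if (!length(claims)) {
    return(tibble::tibble(x = character(), y = character(),
                          conditioning = list()))
  }
  dplyr::bind_rows(claims)
}

#' Fisher's C statistic
#'
#' Combines the p-values of the d-separation basis-set claims:
#' \eqn{C = -2 \sum \log p_i}, chi-square with 2k degrees of freedom under
#' the hypothesized graph.
#'
#' @param p_values Claim p-values, each in (0, 1].
#' @return A list with `C`, `df`, `p`.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0) return(list(C = 0, df = 0, p = 1))
  if (any(p_values <= 0) || any(p_values > 1)) {
    abort("Claim p-values must lie in (0, 1]; p = 0 implies C = +Inf (model rejected).",
          class = "befmeta_degenerate")
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = pchisq(C, df = df, lower.tail = FALSE))
}

#' Stratified resampling of duplicated biodiversity effects
#'
#' Studies often report several biodiversity or abundance effect sizes for
#' the same litter-decomposition measurement.  This draws exactly one
#' biodiversity effect per decomposition measurement (`link_key`), uniformly
#' at random, yielding a table with independent rows for the SEM sub-models.
#'
#' @param paired Paired effect table (see [pair_effects()]): one row per
#'   (decomposition measurement, candidate biodiversity effect).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A tibble with exactly one row per `link_key`.
#' @export
stratified_resample <- function(paired, seed = NULL) {
  if (nrow(paired) == 0) abort("Empty paired-effect table.")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  idx <- resample_indices(split(seq_len(nrow(paired)), paired$link_key))
  paired[sort(idx), ]
}

resample_indices <- function(groups) {
  len <- lengths(groups)
  pick <- pmin(1L + as.integer(floor(runif(length(groups)) * len)), len)
  offset <- cumsum(len) - len
  unlist(groups, use.names = FALSE)[offset + pick]
}

#' Fit the two SEM sub-models on a resampled table
#'
#' Fits one multilevel weighted meta-analytic model per endogenous node of
#' the graph (`zB ~ intensity + study_type + taxon_group (+ diversity_metric)`
#' and `zLD ~ zB + intensity + study_type`), each with known sampling
#' variances and nested case-study/observation random intercepts.
#'
#' @param data A resampled paired table (one biodiversity effect per
#'   decomposition measurement) with columns `zB`, `var_zB`, `zLD`,
#'   `var_zLD`, `intensity`, `study_type`, `taxon_group`,
#'   (`diversity_metric`,) `case_study_id`, `link_key`.
#' @param dag A [sem_dag()]; default the full [mediation_dag()] of `kind`.
#' @param kind `"diversity"` or `"abundance"`.
#' @return A named list of [fit_meta()] objects, one per endogenous node.
#' @export
fit_submodels <- function(data, dag = NULL,
                          kind = c("diversity", "abundance")) {
  kind <- match.arg(kind)
  dag <- dag %||% mediation_dag(kind)
  endo <- setdiff(dag$nodes, dag$exogenous)
  fits <- lapply(setNames(endo, endo), function(nd) {
    rhs <- dag$parents[[nd]]
    f <- as.formula(paste(nd, "~", if (length(rhs))
      paste(rhs, collapse = " + ") else "1"))
    fit_meta(data, f, variance = paste0("var_", nd),
             study = "case_study_id", obs = "link_key")
  })
  fits
}

# Precompute per-model design matrices on the full paired table so each
# resampling iteration only subsets rows (no model.matrix in the hot loop).
sem_model_plan <- function(paired, dag) {
  paired <- as.data.frame(paired)
  chr <- vapply(paired, is.character, logical(1))
  keep_chr <- setdiff(names(paired)[chr], c("link_key", "case_study_id",
                                            "obs_id_B", "obs_id_LD"))
  paired[keep_chr] <- lapply(paired[keep_chr], factor)
  endo <- setdiff(dag$nodes, dag$exogenous)
  claims <- basis_set(dag)
  build <- function(y, rhs, test = NULL) {
    f <- as.formula(paste("~", if (length(rhs)) paste(rhs, collapse = " + ")
                          else "1"))
    mm <- stats::model.matrix(f, paired)
    lab <- attr(terms(f), "term.labels")
    col_map <- lapply(setNames(seq_along(lab), lab),
                      function(i) which(attr(mm, "assign") == i))
    test_cols <- if (!is.null(test)) col_map[[test]] else integer()
    list(y = as.numeric(paired[[y]]), X = mm,
         v = as.numeric(paired[[paste0("var_", y)]]),
         outcome = y, rhs = rhs, col_map = col_map,
         test_cols = test_cols, test = test)
  }
  models <- lapply(setNames(endo, endo),
                   function(nd) build(nd, dag$parents[[nd]]))
  claim_models <- if (nrow(claims)) lapply(seq_len(nrow(claims)), function(i) {
    y <- claims$y[i]; x <- claims$x[i]
    rhs <- c(claims$conditioning[[i]], x)
    m <- build(y, rhs, test = x)
    m$claim_id <- paste0("claim_", i)
    m
  }) else list()
  num_nodes <- Filter(function(nd) is.numeric(paired[[nd]]), dag$nodes)
  list(models = models, claims = claims, claim_models = claim_models,
       g = as.integer(factor(paired$case_study_id)), paired = paired,
       num = lapply(setNames(num_nodes, num_nodes),
                    function(nd) as.numeric(paired[[nd]])))
}

#' Resampling-averaged piecewise SEM
#'
#' Runs the full resampling scheme: at each iteration one biodiversity effect
#' is drawn per decomposition measurement, the sub-models implied by the graph
#' are fitted (REML coefficients and SEs; ML-based AICs), the d-separation
#' basis-set claims are tested (Wald p-value of the omitted predictor added to
#' its child's sub-model), and Fisher's C and the model AIC are recorded.
#' Estimates, SEs, standardized coefficients, C and AIC are averaged
#' arithmetically across iterations; the p-value of the averaged C uses the
#' fixed graph degrees of freedom.  Iterations whose fits fail are skipped;
#' more than 10% failures is an error.
#'
#' @param paired Paired effect table (see [pair_effects()]).
#' @param kind `"diversity"` or `"abundance"`.
#' @param dag A [sem_dag()]; default the full [mediation_dag()] of `kind`.
#' @param iterations Number of resampling iterations (default 1000).
#' @param seed Integer seed controlling the resampling stream.
#' @return An object of class `sem_result`: `paths` (per-edge averaged
#'   unstandardized coefficient, SE, standardized coefficient), `fisher_C`,
#'   `C_df`, `C_p`, `AIC` (sum of sub-model ML AICs, averaged), `indirect_effect`,
#'   `direct_effect`, per-measurement averaged residuals, iteration counts and
#'   the seed.  Supports [tidy()], [glance()], `print()`.
#' @export
run_resampled_sem <- function(paired, kind = c("diversity", "abundance"),
                              dag = NULL, iterations = 1000, seed = 1L) {
  kind <- match.arg(kind)
  dag <- dag %||% mediation_dag(kind)
  stopifnot(iterations >= 1)
  if (nrow(paired) == 0) abort("Empty paired-effect table.")
  plan <- sem_model_plan(paired, dag)
  groups <- split(seq_len(nrow(plan$paired)), plan$paired$link_key)
  n_keys <- length(groups)
  df_C <- 2L * nrow(plan$claims)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  edge_names <- paste(dag$edges$from, dag$edges$to, sep = " -> ")
  coefs <- ses <- stds <- matrix(NA_real_, iterations, nrow(dag$edges),
                                 dimnames = list(NULL, edge_names))
  Cs <- aics <- rep(NA_real_, iterations)
  resid_sum <- lapply(plan$models, function(m) numeric(n_keys))
  resid_cnt <- numeric(n_keys)
  n_failed <- 0L

  warm <- new.env(parent = emptyenv())
  for (it in seq_len(iterations)) {
    idx <- resample_indices(groups)
    res <- tryCatch(sem_iteration(plan, dag, idx, warm),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    coefs[it, ] <- res$coef; ses[it, ] <- res$se; stds[it, ] <- res$std
    Cs[it] <- res$C; aics[it] <- res$aic
    for (m in names(resid_sum)) resid_sum[[m]] <- resid_sum[[m]] + res$resid[[m]]
    resid_cnt <- resid_cnt + 1
  }
  if (n_failed > 0.1 * iterations) {
    abort(sprintf("%d of %d SEM iterations failed to converge.", n_failed,
                  iterations), class = "befmeta_convergence")
  }

  paths <- tibble::tibble(
    from = dag$edges$from, to = dag$edges$to,
    estimate = colMeans(coefs, na.rm = TRUE),
    se = colMeans(ses, na.rm = TRUE),
    std_estimate = colMeans(stds, na.rm = TRUE))
  C_mean <- mean(Cs, na.rm = TRUE)
  C_p <- if (df_C == 0) 1 else pchisq(C_mean, df = df_C, lower.tail = FALSE)

  std_of <- function(from, to) {
    i <- which(paths$from == from & paths$to == to)
    if (length(i)) paths$std_estimate[i] else NA_real_
  }
  indirect <- std_of("intensity", "zB") * std_of("zB", "zLD")
  residuals <- tibble::tibble(link_key = names(groups))
  for (m in names(resid_sum)) {
    residuals[[paste0("resid_", m)]] <- resid_sum[[m]] / pmax(resid_cnt, 1)
  }

  structure(list(
    paths = paths, fisher_C = C_mean, C_df = df_C, C_p = C_p,
    AIC = mean(aics, na.rm = TRUE), indirect_effect = indirect,
    direct_effect = std_of("intensity", "zLD"),
    residuals = residuals, kind = kind, dag = dag,
    n_iterations = iterations, n_failed = n_failed, seed = seed,
    n_measurements = n_keys,
    n_studies = length(unique(plan$paired$case_study_id)),
    data_hash = rlang::hash(paired)), class = "sem_result")
}

# One resampling iteration on precomputed designs: fit each sub-model and each
# claim model on the selected rows; return edge coefficients, claim-based C,
# summed ML AIC, and per-measurement residuals.  `warm` caches the previous
# iteration's variance-component estimates per model as optimizer starts.
sem_iteration <- function(plan, dag, idx, warm = NULL) {
  g <- plan$g[idx]
  fits <- lapply(setNames(names(plan$models), names(plan$models)),
                 function(nm) {
    m <- plan$models[[nm]]
    X <- m$X[idx, , drop = FALSE]
    core <- .fit_meta_core(X, m$y[idx], m$v[idx], g, nested = TRUE,
                           reltol = 1e-8,
                           start = if (!is.null(warm)) warm[[nm]])
    if (!is.null(warm)) warm[[nm]] <- sqrt(pmax(core$sigma2, 1e-8))
    core$resid <- m$y[idx] - drop(X %*% core$beta)
    core
  })
  sd_num <- vapply(plan$num, function(col) sd(col[idx]), numeric(1))

  ne <- nrow(dag$edges)
  co <- se <- st <- rep(NA_real_, ne)
  for (i in seq_len(ne)) {
    to <- dag$edges$to[i]; from <- dag$edges$from[i]
    f <- fits[[to]]
    if (is.null(f)) next
    cols <- plan$models[[to]]$col_map[[from]]
    if (length(cols) != 1L) next  # >2-level categorical: no single coefficient
    co[i] <- f$beta[cols]
    se[i] <- sqrt(f$vcov[cols, cols])
    # standardized coefficient only meaningful for numeric predictors
    if (from %in% names(sd_num) && to %in% names(sd_num)) {
      st[i] <- co[i] * sd_num[[from]] / sd_num[[to]]
    }
  }
  p_claims <- vapply(plan$claim_models, function(m) {
    core <- .fit_meta_core(m$X[idx, , drop = FALSE], m$y[idx], m$v[idx], g,
                           nested = TRUE, ml = FALSE, reltol = 1e-8,
                           start = if (!is.null(warm)) warm[[m$claim_id]])
    if (!is.null(warm)) warm[[m$claim_id]] <- sqrt(pmax(core$sigma2, 1e-8))
    b <- core$beta[m$test_cols]
    Vb <- core$vcov[m$test_cols, m$test_cols, drop = FALSE]
    drop(pchisq(crossprod(b, solve(Vb, b)), df = length(b),
                lower.tail = FALSE))
  }, numeric(1))
  fc <- fishers_c(p_claims)
  list(coef = co, se = se, std = st, C = fc$C,
       aic = sum(vapply(fits, `[[`, 0, "aic_ml")),
       resid = lapply(fits, `[[`, "resid"))
}

#' Mediation test by graph comparison
#'
#' Compares the full SEM with the reduced SEM lacking the biodiversity (or
#' abundance) to decomposition path.  The mediated path is supported when the
#' reduced model fits poorly (p-value of its averaged Fisher's C below 0.05)
#' and the reduced model is not better by more than 2 AIC units.
#'
#' @param full,reduced [run_resampled_sem()] results on the same data, graphs
#'   differing only by the `zB -> zLD` edge.
#' @return A one-row tibble: `supported`, `reduced_C_p`, `delta_AIC`
#'   (= AIC_reduced - AIC_full), the two criteria separately, and a
#'   `criterion_conflict` flag (poor reduced fit yet better reduced AIC).
#' @export
mediation_test <- function(full, reduced) {
  stopifnot(inherits(full, "sem_result"), inherits(reduced, "sem_result"))
  if (!identical(full$data_hash, reduced$data_hash)) {
    abort("Full and reduced SEMs were fitted on different data.")
  }
  e_full <- paste(full$dag$edges$from, full$dag$edges$to)
  e_red <- paste(reduced$dag$edges$from, reduced$dag$edges$to)
  if (!setequal(setdiff(e_full, e_red), "zB zLD") || length(setdiff(e_red, e_full))) {
    abort("Graphs must differ only by the zB -> zLD edge.")
  }
  delta <- reduced$AIC - full$AIC
  poor_reduced_fit <- reduced$C_p < 0.05
  reduced_not_better <- delta > -2
  tibble::tibble(
    supported = poor_reduced_fit && reduced_not_better,
    reduced_C_p = reduced$C_p, delta_AIC = delta,
    poor_reduced_fit = poor_reduced_fit,
    reduced_not_better = reduced_not_better,
    criterion_conflict = poor_reduced_fit && !reduced_not_better)
}

#' Standardize a path coefficient
#'
#' @param coef Unstandardized coefficient.
#' @param sd_predictor,sd_outcome Standard deviations of predictor and
#'   outcome in the analysis table (> 0).
#' @return `coef * sd_predictor / sd_outcome`.
#' @export
standardize_path <- function(coef, sd_predictor, sd_outcome) {
  if (any(sd_predictor <= 0) || any(sd_outcome <= 0)) {
    abort("Standard deviations must be strictly positive.")
  }
  coef * sd_predictor / sd_outcome
}

#' Indirect (mediated) effect
#'
#' The product of the standardized path from driver intensity to the
#' biodiversity response and the standardized path from biodiversity to
#' decomposition; compared in magnitude against the direct intensity ->
#' decomposition path.
#'
#' @param path_intensity_to_b,path_b_to_ld Standardized path coefficients.
#' @return Their product.
#' @export
indirect_effect <- function(path_intensity_to_b, path_b_to_ld) {
  stopifnot(is.finite(path_intensity_to_b), is.finite(path_b_to_ld))
  path_intensity_to_b * path_b_to_ld
}

#' Full mediation analysis for one dataset
#'
#' Convenience wrapper running the full and reduced resampled SEMs and the
#' mediation test.
#'
#' @inheritParams run_resampled_sem
#' @return A list with `full`, `reduced` ([run_resampled_sem()] results) and
#'   `mediation` ([mediation_test()] tibble).
#' @export
run_sem <- function(paired, kind = c("diversity", "abundance"),
                    iterations = 1000, seed = 1L) {
  kind <- match.arg(kind)
  full <- run_resampled_sem(paired, kind, mediation_dag(kind, TRUE),
                            iterations = iterations, seed = seed)
  reduced <- run_resampled_sem(paired, kind, mediation_dag(kind, FALSE),
                               iterations = iterations, seed = seed)
  list(full = full, reduced = reduced,
       mediation = mediation_test(full, reduced))
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("Piecewise SEM (%s), %d measurements in %d studies, %d iterations (%d failed)\n",
              x$kind, x$n_measurements, x$n_studies, x$n_iterations,
              x$n_failed))
  print(x$paths, ...)
  cat(sprintf("Fisher's C = %.3f (df = %d), p = %.4g; AIC = %.2f\n",
              x$fisher_C, x$C_df, x$C_p, x$AIC))
  cat(sprintf("Indirect effect = %.4f; direct effect = %.4f\n",
              x$indirect_effect, x$direct_effect))
  invisible(x)
}
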