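#' Assemble the mixed-model equations of the repeatability animal model
#'
#' Builds Henderson's mixed-model equations for
#' \deqn{y = Xb + Za + Wpe + e,\qquad a \sim N(0, K\sigma^2_a),\quad
#'   pe \sim N(0, I\sigma^2_{pe}),\quad e \sim N(0, I\sigma^2_e),}
#' where X carries the fixed effects and covariates from \code{formula}, Z
#' maps each record to its animal (the full pedigree, via the supplied
#' relationship inverse \code{kinv}), and W maps each record to its animal's
#' permanent-environment effect (animals with records only). The coefficient
#' matrix is kept in variance-ratio form,
#' \deqn{\begin{bmatrix} X'X & X'Z & X'W \\ Z'X & Z'Z + K^{-1} k_a & Z'W \\
#'   W'X & W'Z & W'W + I k_p \end{bmatrix},\qquad
#'   k_a = \sigma^2_e/\sigma^2_a,\; k_p = \sigma^2_e/\sigma^2_{pe}.}
#' Aliased fixed-effect columns are dropped (one level per confounded
#' class); year-season levels without records are dropped with a warning.
#'
#' @param formula model formula, response on the left, fixed-effect classes
#'   and covariates on the right (e.g. \code{y ~ yearseason + age + intv}).
#' @param data data.frame of records with an \code{id} column linking each
#'   record to an animal.
#' @param kinv relationship inverse over all animals (sparse
#'   \eqn{A^{-1}} or \eqn{H^{-1}}), with dimnames = animal ids.
#' @param varcomp named vector (or \code{\link{reml_ai}} fit) with
#'   \code{var_a}, \code{var_pe}, \code{var_e}.
#' @param id name of the animal-id column in \code{data}.
#' @param pe include the permanent-environment effect (\code{FALSE} only
#'   sensible for single-record data).
#' @return object of class \code{"mme"}: coefficient matrix \code{C}
#'   (sparse, ratio form), right-hand side, design components and block
#'   index maps.
#' @export
build_mme <- function(formula, data, kinv, varcomp, id = "id", pe = TRUE) {
  vc <- as_varcomp(varcomp, need_pe = pe)
  stopifnot(id %in% names(data))
  ids_all <- rownames(kinv)
  if (is.null(ids_all)) stop("kinv needs dimnames (animal ids)")
  ai <- match(as.character(data[[id]]), ids_all)
  if (anyNA(ai))
    stop("record animal id(s) not in the relationship matrix: ",
         paste(utils::head(unique(data[[id]][is.na(ai)]), 5L), collapse = ", "))
  mf_data <- data
  for (v in all.vars(formula[[3L]]))
    if (is.factor(mf_data[[v]]) && nlevels(droplevels(mf_data[[v]])) <
        nlevels(mf_data[[v]])) {
      warning("dropping empty levels of '", v, "'")
      mf_data[[v]] <- droplevels(mf_data[[v]])
    }
  mf <- stats::model.frame(formula, mf_data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  n <- length(y)
  qa <- length(ids_all)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ai, x = 1, dims = c(n, qa))
  if (pe) {
    pe_ids <- sort(unique(ai))
    wi <- match(ai, pe_ids)
    W <- Matrix::sparseMatrix(i = seq_len(n), j = wi, x = 1,
                              dims = c(n, length(pe_ids)))
  } else {
    pe_ids <- integer(0)
    W <- NULL
  }
  M <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  if (pe) M <- cbind(M, W)
  ka <- vc["var_e"] / vc["var_a"]
  kp <- if (pe) vc["var_e"] / vc["var_pe"] else NA_real_
  p <- ncol(X)
  nc <- p + qa + length(pe_ids)
  pen <- ka * kinv
  if (pe) pen <- Matrix::bdiag(pen, kp * Matrix::Diagonal(length(pe_ids)))
  C <- Matrix::crossprod(M) +
    Matrix::bdiag(Matrix::Matrix(0, p, p), pen)
  rhs <- Matrix::crossprod(M, y)
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, M = M, y = y,
                 X = X, animal_idx = ai, pe_idx = if (pe) wi else NULL,
                 blocks = list(fix = seq_len(p),
                               animal = p + seq_len(qa),
                               pe = if (pe) p + qa + seq_along(pe_ids)
                                    else integer(0)),
                 animal_ids = ids_all,
                 pe_ids = ids_all[pe_ids],
                 varcomp = vc, kinv = kinv, pe = pe),
            class = "mme")
}

# normalise variance-component input
as_varcomp <- function(varcomp, need_pe = TRUE) {
  if (inherits(varcomp, "reml_fit")) varcomp <- varcomp$varcomp
  varcomp <- unlist(varcomp)
  need <- c("var_a", if (need_pe) "var_pe", "var_e")
  if (!all(need %in% names(varcomp)))
    stop("varcomp needs named components: ", paste(need, collapse = ", "))
  if (any(varcomp[need] <= 0))
    stop("variance components must be positive for the MME ratios")
  varcomp
}

#' Solve assembled mixed-model equations
#'
#' Default is a sparse Cholesky factorisation (CHOLMOD); a Jacobi-
#' preconditioned conjugate-gradient solver is available for very large
#' systems.
#'
#' @param system an \code{\link{build_mme}} object.
#' @param method \code{"chol"} or \code{"pcg"}.
#' @param tol,max_iter convergence control for \code{"pcg"} (relative
#'   residual norm).
#' @return object of class \code{"mme_solutions"}: fixed-effect estimates
#'   \code{b}, breeding values \code{a} (all animals), permanent-environment
#'   solutions \code{p}, record residuals and the achieved residual norm of
#'   the linear system.
#' @export
solve_mme <- function(system, method = c("chol", "pcg"), tol = 1e-10,
                      max_iter = 2000L) {
  method <- match.arg(method)
  C <- system$C; rhs <- system$rhs
  if (method == "chol") {
    sol <- as.numeric(Matrix::solve(Matrix::Cholesky(C, LDL = FALSE), rhs))
  } else {
    sol <- pcg_solve(C, as.numeric(rhs), tol = tol, max_iter = max_iter)
  }
  rnorm_ <- sqrt(sum(as.numeric(C %*% sol - rhs)^2)) /
    max(sqrt(sum(as.numeric(rhs)^2)), 1e-300)
  b <- sol[system$blocks$fix]
  names(b) <- colnames(system$X)
  a <- sol[system$blocks$animal]
  names(a) <- system$animal_ids
  p <- if (system$pe) stats::setNames(sol[system$blocks$pe], system$pe_ids)
       else numeric(0)
  fitted <- as.numeric(system$M %*% sol)
  structure(list(b = b, a = a, p = p, solution = sol,
                 fitted = fitted, residuals = system$y - fitted,
                 residual_norm = rnorm_),
            class = "mme_solutions")
}

#' @export
print.mme_solutions <- function(x, ...) {
  cat("MME solutions:", length(x$b), "fixed effects,", length(x$a),
      "breeding values,", length(x$p), "permanent-environment effects\n")
  cat("  relative residual norm:", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems
pcg_solve <- function(C, b, tol = 1e-10, max_iter = 2000L) {
  d <- Matrix::diag(C)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    res <- sqrt(sum(r^2)) / bn
    hist <- c(hist, res)
    if (res < tol) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("PCG did not converge in ", max_iter,
       " iterations; last residuals: ",
       paste(format(utils::tail(hist, 5L), digits = 3), collapse = ", "))
}

#' Average-information REML for the repeatability animal model
#'
#' Estimates \eqn{(\sigma^2_a, \sigma^2_{pe}, \sigma^2_e)} by restricted
#' maximum likelihood with average-information (AI) updates and an
#' expectation-maximisation fallback whenever an AI step would leave the
#' parameter space. First derivatives use the standard mixed-model-equation
#' trace identities; the AI matrix is built from the working vectors
#' \eqn{Z\hat a/\sigma^2_a}, \eqn{W\hat{pe}/\sigma^2_{pe}} and
#' \eqn{\hat e/\sigma^2_e}, each projected through an extra MME solve.
#' Standard errors come from the inverse AI matrix at convergence.
#' Components are kept above a small positive floor; estimates ending on the
#' floor indicate a boundary solution.
#'
#' @inheritParams build_mme
#' @param start optional starting values (named like the result); default is
#'   equal thirds of the phenotypic variance.
#' @param tol convergence tolerance on the maximum relative parameter
#'   change.
#' @param max_iter iteration cap.
#' @param verbose print the per-iteration log.
#' @return object of class \code{"reml_fit"}: \code{varcomp}, \code{se},
#'   \code{ai} matrix, restricted log-likelihood (up to a constant),
#'   iteration log, convergence flag and \code{\link{heritability}} summary.
#' @export
reml_ai <- function(formula, data, kinv, id = "id", pe = TRUE,
                    start = NULL, tol = 1e-8, max_iter = 50L,
                    verbose = FALSE) {
  stopifnot(id %in% names(data))
  if (pe) {
    nrec <- table(as.character(data[[id]]))
    if (max(nrec) < 2L)
      stop("no animal has repeated records: the permanent-environment ",
           "variance is not identifiable (set pe = FALSE)")
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  vp0 <- stats::var(y)
  floor_ <- 1e-8 * vp0
  theta <- if (is.null(start)) {
    k <- if (pe) 3 else 2
    stats::setNames(rep(vp0 / 3, k),
                    c("var_a", if (pe) "var_pe", "var_e"))
  } else as_varcomp(start, need_pe = pe)
  n_par <- length(theta)
  log_lines <- data.frame()
  converged <- FALSE
  last <- NULL
  for (iter in seq_len(max_iter)) {
    st <- reml_step(formula, data, kinv, theta, id = id, pe = pe)
    if (!is.null(last) && st$loglik < last$loglik - 1e-6) {
      # the projected AI step overshot: back up and take an EM step from
      # the previous (better) point instead
      theta <- stats::setNames(pmax(last$em, floor_), names(theta))
      if (verbose)
        message(sprintf("it %2d [EM backtrack] logL=%.6f -> restart", iter,
                        st$loglik))
      log_lines <- rbind(log_lines,
                         data.frame(iter = iter, step = "EM-backtrack",
                                    loglik = st$loglik,
                                    t(theta), rel_change = NA_real_))
      last <- NULL
      next
    }
    delta <- tryCatch(solve(st$ai, st$score), error = function(e) NULL)
    if (is.null(delta)) {
      prop <- st$em
      used <- "EM"
    } else {
      prop <- theta + delta
      used <- "AI"
      if (any(prop <= 0)) {
        # Newton step leaves the parameter space: project onto the
        # boundary (floored); EM backtracking above guards the likelihood
        prop <- pmax(prop, floor_)
        used <- "AI-proj"
      }
    }
    prop <- pmax(prop, floor_)
    # relative change, with near-boundary components measured against a
    # small fraction of the phenotypic variance so they cannot stall
    # convergence
    rel <- max(abs(prop - theta) / pmax(abs(theta), 1e-4 * vp0))
    log_lines <- rbind(log_lines,
                       data.frame(iter = iter, step = used,
                                  loglik = st$loglik,
                                  t(stats::setNames(prop, names(theta))),
                                  rel_change = rel))
    if (verbose)
      message(sprintf("it %2d [%s] logL=%.6f  %s  rel=%.2e", iter, used,
                      st$loglik,
                      paste(sprintf("%.6g", prop), collapse = " "), rel))
    last <- list(loglik = st$loglik, em = st$em)
    theta <- stats::setNames(prop, names(theta))
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("AI-REML reached max_iter without meeting tol = ", tol)
  st <- reml_step(formula, data, kinv, theta, id = id, pe = pe)
  se <- tryCatch(sqrt(diag(solve(st$ai))), error = function(e)
    rep(NA_real_, n_par))
  names(se) <- names(theta)
  fit <- structure(list(varcomp = theta, se = se, ai = st$ai,
                        loglik = st$loglik, iterations = nrow(log_lines),
                        log = log_lines, converged = converged,
                        n_records = length(y),
                        boundary = theta <= floor_ * (1 + 1e-6),
                        call = match.call()),
                   class = "reml_fit")
  fit
}

# One AI-REML evaluation at theta: score, AI matrix, EM update, loglik.
# Uses the MME in ratio form; C_ratio^{-1} * var_e is the unscaled inverse.
reml_step <- function(formula, data, kinv, theta, id = "id", pe = TRUE) {
  va <- theta[["var_a"]]
  vp <- if (pe) theta[["var_pe"]] else NA_real_
  ve <- theta[["var_e"]]
  sys <- build_mme(formula, data, kinv, theta, id = id, pe = pe)
  nc <- nrow(sys$C)
  if (nc > 12000L)
    stop("MME too large for the dense-inverse REML path (", nc, " equations)")
  Ch <- Matrix::Cholesky(sys$C, LDL = FALSE)
  sol <- as.numeric(Matrix::solve(Ch, sys$rhs))
  y <- sys$y
  N <- length(y)
  p_fix <- length(sys$blocks$fix)
  e_hat <- y - as.numeric(sys$M %*% sol)
  a_hat <- sol[sys$blocks$animal]
  pe_hat <- sol[sys$blocks$pe]
  qa <- length(a_hat); qp <- length(pe_hat)
  # inverse of the ratio-form coefficient matrix (dense)
  Cinv <- as.matrix(Matrix::solve(Ch, diag(nc)))
  Kg <- methods::as(methods::as(kinv, "generalMatrix"), "TsparseMatrix")
  caa <- Cinv[sys$blocks$animal, sys$blocks$animal]
  tr_kinv_caa <- sum(Kg@x * caa[cbind(Kg@i + 1L, Kg@j + 1L)])
  tr_cpp <- if (pe) sum(diag(Cinv)[sys$blocks$pe]) else 0
  kinv_a <- as.numeric(kinv %*% a_hat)
  aKa <- sum(a_hat * kinv_a)
  # trace identities:  tr(P Zdot) with C^{xx}_unscaled = ve * Cinv_ratio
  trPVa <- qa / va - ve * tr_kinv_caa / va^2
  trPVp <- if (pe) qp / vp - ve * tr_cpp / vp^2 else 0
  trP <- (N - p_fix - va * trPVa - ifelse(pe, vp * trPVp, 0)) / ve
  yPVaPy <- aKa / va^2
  yPVpPy <- if (pe) sum(pe_hat^2) / vp^2 else 0
  yPPy <- sum(e_hat^2) / ve^2
  score <- c(var_a = -0.5 * (trPVa - yPVaPy),
             var_pe = if (pe) -0.5 * (trPVp - yPVpPy),
             var_e = -0.5 * (trP - yPPy))
  # AI matrix from projected working vectors
  t_list <- list(var_a = a_hat[sys$animal_idx] / va,
                 var_pe = if (pe) pe_hat[sys$pe_idx] / vp,
                 var_e = e_hat / ve)
  t_list <- t_list[!vapply(t_list, is.null, logical(1))]
  Pt <- lapply(t_list, function(t_) {
    rhs_t <- Matrix::crossprod(sys$M, t_)
    sol_t <- as.numeric(Matrix::solve(Ch, rhs_t))
    (t_ - as.numeric(sys$M %*% sol_t)) / ve
  })
  k <- length(t_list)
  ai <- matrix(0, k, k, dimnames = list(names(t_list), names(t_list)))
  for (i in seq_len(k)) for (j in i:k)
    ai[i, j] <- ai[j, i] <- 0.5 * sum(t_list[[i]] * Pt[[j]])
  # EM updates (guaranteed in-bounds)
  em <- c(var_a = (aKa + ve * tr_kinv_caa) / qa,
          var_pe = if (pe) (sum(pe_hat^2) + ve * tr_cpp) / qp,
          var_e = (sum(e_hat^2) +
                     ve * (nc - ve * (tr_kinv_caa / va +
                                        ifelse(pe, tr_cpp / vp, 0)))) / N)
  # restricted log-likelihood up to a constant:
  # -2L = log|C_un| + qa log va + qp log vp + N log ve + y'Py  (+ const)
  ldetC_r <- as.numeric(Matrix::determinant(sys$C, logarithm = TRUE)$modulus)
  ldetC_un <- ldetC_r - nc * log(ve)
  yPy <- sum(y * e_hat) / ve
  loglik <- -0.5 * (ldetC_un + qa * log(va) + ifelse(pe, qp * log(vp), 0) +
                      N * log(ve) + yPy)
  list(score = score, ai = ai, em = em, loglik = loglik)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- cbind(estimate = x$varcomp, se = x$se)
  print(round(tab, 6))
  h <- heritability(x)
  cat(sprintf("h2 = %.5f, repeatability = %.5f\n", h["h2"],
              h["repeatability"]))
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  out <- list(varcomp = object$varcomp, se = object$se,
              heritability = heritability(object),
              loglik = object$loglik, converged = object$converged,
              iterations = object$iterations, log = object$log)
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  cat("Variance components (AI-REML)\n")
  print(cbind(estimate = x$varcomp, se = x$se))
  cat(sprintf("h2 = %.5f  repeatability = %.5f  logL = %.4f\n",
              x$heritability["h2"], x$heritability["repeatability"],
              x$loglik))
  invisible(x)
}

#' Heritability and repeatability under the repeatability model
#'
#' \deqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e),\qquad
#'   r = (\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a + \sigma^2_{pe} +
#'   \sigma^2_e).}
#'
#' @param varcomp named vector (\code{var_a}, \code{var_pe}, \code{var_e}),
#'   unnamed length-3 vector in that order, or a \code{\link{reml_ai}} fit.
#' @return named vector with \code{h2} and \code{repeatability}.
#' @examples
#' heritability(c(0.00757, 0.00248, 0.03695))  # ~0.16105
#' @export
heritability <- function(varcomp) {
  if (inherits(varcomp, "reml_fit")) varcomp <- varcomp$varcomp
  v <- unlist(varcomp)
  if (is.null(names(v)) || !all(c("var_a", "var_e") %in% names(v))) {
    if (length(v) != 3L)
      stop("expected var_a, var_pe, var_e")
    names(v) <- c("var_a", "var_pe", "var_e")
  }
  if (!"var_pe" %in% names(v)) v["var_pe"] <- 0
  if (any(v < 0)) stop("negative variance component")
  tot <- sum(v[c("var_a", "var_pe", "var_e")])
  if (tot <= 0) stop("total variance is zero")
  c(h2 = unname(v["var_a"] / tot),
    repeatability = unname((v["var_a"] + v["var_pe"]) / tot))
}
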