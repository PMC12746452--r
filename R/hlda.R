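#' Per-class descriptor statistics
#'
#' Sample mean and unbiased (n-1) covariance of the frames carrying a given
#' class label.
#'
#' @param series labelled \code{DescriptorSeries}.
#' @param label class label to select.
#' @return list with \code{mu}, \code{sigma}, \code{n}.
#' @export
classStatistics <- function(series, label) {
  stopifnot(is(series, "DescriptorSeries"))
  if (!length(series@label)) stop("descriptor series carries no class labels")
  sel <- series@label == label
  if (sum(sel) < 2L)
    stop(sprintf("need >= 2 samples with label '%s' (have %d)", label, sum(sel)))
  x <- series@values[sel, , drop = FALSE]
  list(mu = colMeans(x), sigma = cov(x), n = sum(sel))
}

#' Between-class scatter matrix
#'
#' \eqn{S_b = (\mu_A - \mu_B)(\mu_A - \mu_B)^T}: symmetric, positive
#' semi-definite, rank at most 1; its trace equals
#' \eqn{\|\mu_A - \mu_B\|^2}.
#'
#' @param statsA,statsB outputs of \code{\link{classStatistics}}.
#' @return d x d matrix.
#' @export
betweenScatter <- function(statsA, statsB) {
  if (length(statsA$mu) != length(statsB$mu)) stop("dimension mismatch between classes")
  d <- statsA$mu - statsB$mu
  outer(d, d)
}

#' Harmonic within-class scatter
#'
#' \eqn{S_w = (\Sigma_A^{-1} + \Sigma_B^{-1})^{-1}} after adding a ridge to
#' each covariance. The harmonic mean penalizes directions in which either
#' class is tight, which is what makes the discriminant a good biasing
#' coordinate: it favours directions along which both basins are narrow.
#'
#' @param statsA,statsB outputs of \code{\link{classStatistics}}.
#' @param ridge nonnegative regularizer added as \code{ridge * I} to each
#'   covariance before inversion; default \code{1e-8 * mean(diag)} of the
#'   pooled covariance.
#' @return symmetric positive-definite matrix.
#' @export
harmonicWithinScatter <- function(statsA, statsB, ridge = NULL) {
  SA <- as.matrix(statsA$sigma); SB <- as.matrix(statsB$sigma)
  if (!all(dim(SA) == dim(SB))) stop("dimension mismatch between classes")
  d <- nrow(SA)
  if (is.null(ridge)) ridge <- 1e-8 * (sum(diag(SA)) + sum(diag(SB))) / (2 * d)
  SA <- SA + ridge * diag(d); SB <- SB + ridge * diag(d)
  inv <- function(S, nm) tryCatch(solve(S), error = function(e)
    stop(sprintf("covariance %s is singular even after ridge %g; increase the ridge", nm, ridge)))
  Sw <- tryCatch(solve(inv(SA, "sigmaA") + inv(SB, "sigmaB")),
                 error = function(e)
                   stop(sprintf("within-class scatter singular after ridge %g; increase the ridge", ridge)))
  (Sw + t(Sw)) / 2
}

#' Fit the HLDA discriminant direction
#'
#' Solves the generalized eigenproblem \eqn{S_w^{-1} S_b W = \lambda W} via
#' the symmetric form \eqn{S_w^{-1/2} S_b S_w^{-1/2}}. Because \eqn{S_b} has
#' rank 1, exactly one eigenvalue is nonzero:
#' \eqn{\lambda_1 = \Delta\mu^T S_w^{-1} \Delta\mu}, with leading eigenvector
#' proportional to \eqn{S_w^{-1} \Delta\mu}. The returned weight vector is
#' unit-norm with its largest-magnitude component negative (the conventional
#' all-negative sign of the published discriminant weights).
#'
#' @param statsA,statsB outputs of \code{\link{classStatistics}} for the
#'   folded (A) and unfolded (B) ensembles.
#' @param ridge see \code{\link{harmonicWithinScatter}}.
#' @param descriptorNames ordering metadata stored with the model.
#' @return \code{\linkS4class{HLDAModel}}.
#' @export
hldaDirection <- function(statsA, statsB, ridge = NULL,
                          descriptorNames = paste0("d", seq_along(statsA$mu))) {
  Sw <- harmonicWithinScatter(statsA, statsB, ridge)
  dmu <- statsA$mu - statsB$mu
  d <- length(dmu)
  if (vnorm(dmu) < 1e-14) {
    return(new("HLDAModel", weights = rep(0, d), eigenvalues = rep(0, d),
               eigenvectors = diag(d), separation = 0,
               descriptorNames = descriptorNames, degenerate = TRUE))
  }
  eSw <- eigen(Sw, symmetric = TRUE)
  SwInvHalf <- eSw$vectors %*% diag(1 / sqrt(eSw$values)) %*% t(eSw$vectors)
  Sb <- outer(dmu, dmu)
  M <- SwInvHalf %*% Sb %*% SwInvHalf
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(eM$values, decreasing = TRUE)
  lambda <- eM$values[ord]
  vecs <- SwInvHalf %*% eM$vectors[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2, apply(vecs, 2, vnorm), "/")
  w <- vecs[, 1]
  if (w[which.max(abs(w))] > 0) w <- -w
  vecs[, 1] <- w
  new("HLDAModel", weights = w, eigenvalues = lambda, eigenvectors = vecs,
      separation = sum(dmu * solve(Sw, dmu)),
      descriptorNames = descriptorNames, degenerate = FALSE)
}

#' Fit HLDA from a labelled descriptor series
#'
#' Convenience wrapper: class statistics for the two labels, then
#' \code{\link{hldaDirection}}.
#'
#' @param series labelled \code{DescriptorSeries} (exactly two labels).
#' @param labels the two class labels, folded first.
#' @param ridge see \code{\link{harmonicWithinScatter}}.
#' @return \code{\linkS4class{HLDAModel}}.
#' @export
hldaFit <- function(series, labels = NULL, ridge = NULL) {
  labs <- unique(series@label)
  if (is.null(labels)) labels <- sort(labs)
  if (length(labels) != 2L) stop("HLDA requires exactly two class labels")
  hldaDirection(classStatistics(series, labels[1]),
                classStatistics(series, labels[2]), ridge = ridge)
}

#' Project descriptors onto the HLDA collective variable
#'
#' Per-frame dot product \eqn{s(R) = W^* \cdot d(R)}; linear in the
#' descriptors. Refuses silently reordered input: descriptor column names,
#' when present, must match the model's metadata.
#'
#' @param model \code{HLDAModel}.
#' @param series \code{DescriptorSeries} or a frames x d matrix.
#' @return numeric CV vector, one value per frame.
#' @export
projectCV <- function(model, series) {
  x <- if (is(series, "DescriptorSeries")) series@values else as.matrix(series)
  if (ncol(x) != length(model@weights)) stop("descriptor dimension mismatch")
  cn <- colnames(x)
  if (!is.null(cn) && !identical(cn, model@descriptorNames))
    stop("descriptor ordering does not match the model (refusing silent reordering)")
  as.numeric(x %*% model@weights)
}

#' Export the fitted CV as a plain-text linear-combination definition
#'
#' One coefficient per line (\code{label coefficient}); round-trippable by
#' \code{\link{parseCVDefinition}}.
#'
#' @param model fitted, non-degenerate \code{HLDAModel}.
#' @param file optional path; when missing the text is returned.
#' @return character vector of lines (invisibly when written to file).
#' @export
exportCVDefinition <- function(model, file = NULL) {
  if (model@degenerate) stop("cannot export a degenerate (unfitted) model")
  lines <- c("# linear combination collective variable",
             sprintf("%s %.17g", model@descriptorNames, model@weights))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a linear-combination CV definition
#'
#' @param lines character vector of lines, or a file path.
#' @return \code{HLDAModel} carrying the parsed weights (eigen-spectrum of
#'   the source fit is not part of the interchange format).
#' @export
parseCVDefinition <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nms <- vapply(parts, `[[`, "", 1L)
  w <- as.numeric(vapply(parts, `[[`, "", 2L))
  d <- length(w)
  new("HLDAModel", weights = w, eigenvalues = c(1, rep(0, d - 1L)),
      eigenvectors = diag(d), separation = NA_real_,
      descriptorNames = nms, degenerate = FALSE)
}
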