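#' Export a BUGS/JAGS model and data bundle
#'
#' Writes the family mixed model in the independent-random-effects
#' parameterization as BUGS language text plus a matching data file, so the
#' model can be run unchanged in OpenBUGS or JAGS. The likelihood loops over
#' families and over individuals within each family via the `offset` vector;
#' the polygenic contribution is the inner product of the offset-sliced row
#' of `G` with the offset slice of `u`; `u` components get univariate normal
#' priors with precision `tau.g`; fixed effects get `dnorm(0, 0.001)` priors
#' and precisions `dgamma(1, 1)` priors by default. The Gaussian model
#' carries `tau.e` and a derived narrow-sense heritability node; the
#' Bernoulli model replaces the normal likelihood by `dbern` with a logit
#' link and drops `tau.e`.
#'
#' @param spec an [lmm_spec()] or [glmm_spec()].
#' @param prior a [prior_spec()].
#' @param covariate_names names for the non-intercept columns of `X`, used
#'   as data vector names and `b.<name>` coefficient names. Must not collide
#'   with the reserved symbols `y`, `u`, `G`, `offset`, `mu`, `p`, `b0`,
#'   `tau.e`, `tau.g`, `N`, `n.fam`.
#' @return Object of class `bugs_bundle`: list with `model_text`,
#'   `data_text`, `inits_text`.
#' @seealso [write_bugs()], [read_bugs_data()]
#' @export
export_bugs <- function(spec, prior = prior_spec(), covariate_names = NULL) {
  binary <- inherits(spec, "glmm_spec")
  if (!binary && !inherits(spec, "lmm_spec"))
    stop("spec must be an lmm_spec or glmm_spec")
  p <- ncol(spec$X)
  if (is.null(covariate_names)) {
    covariate_names <- if (p > 1L) {
      cn <- colnames(spec$X)[-1L]
      if (is.null(cn)) sprintf("x%d", seq_len(p - 1L)) else cn
    } else character(0)
  }
  if (length(covariate_names) != p - 1L)
    stop("need ", p - 1L, " covariate names, got ", length(covariate_names))
  reserved <- c("y", "u", "G", "offset", "mu", "p", "b0", "tau.e", "tau.g",
                "N", "n.fam")
  clash <- intersect(covariate_names, reserved)
  if (length(clash) > 0L)
    stop("covariate name(s) collide with reserved symbols: ",
         paste(clash, collapse = ", "))

  model_text <- bugs_model_text(covariate_names, prior, binary)
  off <- spec$off
  dat <- list(N = off$N, `n.fam` = off$n_fam, offset = off$offsets,
              y = spec$y)
  for (k in seq_along(covariate_names))
    dat[[covariate_names[k]]] <- spec$X[, k + 1L]
  dat$G <- loading_as_matrix(spec$G)
  data_text <- rdump_text(dat)

  inits <- list(b0 = 0)
  for (nm in covariate_names) inits[[paste0("b.", nm)]] <- 0
  inits$u <- rep(0, off$N)
  inits$tau.g <- 1
  if (!binary) inits$tau.e <- 1
  inits_text <- rdump_text(inits)

  structure(list(model_text = model_text, data_text = data_text,
                 inits_text = inits_text, binary = binary),
            class = "bugs_bundle")
}

bugs_model_text <- function(covs, prior, binary) {
  bterm <- if (length(covs) > 0L)
    paste0(" + ", paste0("b.", covs, "*", covs, "[j]", collapse = " + "))
  else ""
  inprod <- paste0("inprod(G[j, offset[i]:(offset[i+1]-1)], ",
                   "u[offset[i]:(offset[i+1]-1)])")
  lik <- if (binary) c(
    "         y[j] ~ dbern(p[j])",
    paste0("         logit(p[j]) <- b0", bterm, " + "),
    paste0("            ", inprod)
  ) else c(
    "         y[j] ~ dnorm( mu[j], tau.e)",
    paste0("         mu[j] <- b0", bterm, " + "),
    paste0("            ", inprod)
  )
  pr_b <- sprintf("dnorm(%s,%s)", format(prior$beta_mean),
                  format(prior$beta_precision))
  pr_t <- sprintf("dgamma(%s, %s)", format(prior$tau_shape),
                  format(prior$tau_rate))
  lines <- c(
    "model svd {",
    "   ## loop over families",
    "   for( i in 1:n.fam) {",
    "      ## loop over individuals within each family",
    "      for( j in offset[i]:(offset[i+1] - 1) ) {",
    lik,
    "      }",
    "   }",
    "   ## model random effects as univariate normal",
    "   for( t in 1:N) { u[t] ~ dnorm( 0, tau.g) }",
    "   ## priors for fixed effects",
    paste0("   b0 ~ ", pr_b),
    if (length(covs) > 0L) paste0("   b.", covs, " ~ ", pr_b),
    "   ## variance components",
    if (!binary) paste0("   tau.e ~ ", pr_t),
    paste0("   tau.g ~ ", pr_t),
    "   sigma.g2 <- 1/tau.g",
    if (!binary) c(
      "   sigma.e2 <- 1/tau.e",
      "   ## narrow-sense heritability",
      "   herit <- (1/tau.g)/( 1/tau.g+1/tau.e)"),
    "}")
  paste(lines, collapse = "\n")
}

# R-dump serialization; matrices are written ROW-major with an explicit
# .Dim attribute (the layout OpenBUGS expects for rectangular data).
rdump_text <- function(x) {
  fmt_num <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "NA" else format(z, digits = 17, scientific = FALSE)
    }, character(1))
    out
  }
  entries <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (is.matrix(v)) {
      vals <- paste(fmt_num(as.vector(t(v))), collapse = ", ")
      sprintf("\"%s\" <- structure(c(%s), .Dim = c(%d, %d))",
              nm, vals, nrow(v), ncol(v))
    } else if (length(v) == 1L) {
      sprintf("\"%s\" <- %s", nm, fmt_num(v))
    } else {
      sprintf("\"%s\" <- c(%s)", nm, paste(fmt_num(v), collapse = ", "))
    }
  }, character(1))
  paste0(paste(entries, collapse = "\n"), "\n")
}

#' Write a BUGS bundle to a directory
#'
#' Writes `model.txt`, `data.txt` and `inits.txt`.
#'
#' @param bundle a `bugs_bundle` from [export_bugs()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bugs <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bugs_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("model.txt", "data.txt", "inits.txt"))
  writeLines(bundle$model_text, paths[1L])
  writeLines(bundle$data_text, paths[2L])
  writeLines(bundle$inits_text, paths[3L])
  invisible(paths)
}

#' Parse an R-dump BUGS data file
#'
#' Reads files produced by [export_bugs()] (or any scalar/vector/
#' `structure(.Dim)` R-dump). Matrices are interpreted as row-major, the
#' convention used by the exporter.
#'
#' @param path file path or a character string of R-dump text.
#' @return Named list of scalars, vectors and matrices.
#' @export
read_bugs_data <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path))
    paste(readLines(path), collapse = "\n") else paste(path, collapse = "\n")
  env <- new.env(parent = baseenv())
  eval(parse(text = txt), envir = env)
  out <- mget(ls(env), envir = env)
  lapply(out, function(v) {
    if (is.matrix(v))  # undo row-major storage
      matrix(as.vector(v), nrow = nrow(v), ncol = ncol(v), byrow = TRUE)
    else v
  })
}

#' @export
print.bugs_bundle <- function(x, ...) {
  cat("BUGS bundle (", if (x$binary) "bernoulli-logit" else "gaussian",
      " likelihood)\n", sep = "")
  cat(x$model_text, "\n")
  invisible(x)
}
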