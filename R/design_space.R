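#' @name design_space
#' @title Design-space model selection over regulation architectures
#'
#' @description
#' A regulation scheme assigns, to each of the five regulated quantities
#' (p0, p1, q1, eta1, eta2), either no regulation or regulation by one of
#' the four cell types (S, P, TDl, TDm) with a sign. That gives 9 options
#' per quantity and `9^5 = 59049` candidate architectures. Each candidate
#' is decomposed into its dominant power-law subsystems (S-systems): per
#' ODE one dominant source and one dominant sink term, and per regulated
#' Hill term one asymptotic branch (`gamma * X` below or above 1). A
#' subsystem survives if its log-linear equilibrium exists, all dominance
#' and regime inequalities hold strictly there, and the subsystem Jacobian
#' is stable. A scheme is viable if at least one subsystem survives for at
#' least one point of a fixed, broad parameter sample.
NULL

QUANTITIES <- c("p0", "p1", "q1", "eta1", "eta2")
CELLS <- c("S", "P", "TDl", "TDm")

# scheme entry codes: 0 = none; 1..8 = (source-1)*2 + sign,
# source in 1:4 (S,P,TDl,TDm), sign 1 = negative, 2 = positive.
code_from_string <- function(s) {
  if (s == "none") return(0L)
  sign <- substring(s, nchar(s))
  src <- substring(s, 1, nchar(s) - 1)
  if (!src %in% CELLS || !sign %in% c("-", "+"))
    stop("bad regulation spec: ", s)
  (match(src, CELLS) - 1L) * 2L + ifelse(sign == "-", 1L, 2L)
}

code_to_string <- function(code) {
  vapply(as.integer(code), function(cd) {
    if (cd == 0L) "none" else
      paste0(CELLS[(cd - 1L) %/% 2L + 1L],
             c("-", "+")[(cd - 1L) %% 2L + 1L])
  }, character(1))
}

#' Construct a regulation scheme
#'
#' @param p0,p1,q1,eta1,eta2 each `"none"` or a string `"<cell><sign>"`,
#'   e.g. `"P-"` (negative regulation by MPPs) or `"TDm+"`.
#' @return Integer code vector of length 5, class `regulation_scheme`.
#' @export
regulation_scheme <- function(p0 = "none", p1 = "none", q1 = "none",
                              eta1 = "none", eta2 = "none") {
  codes <- vapply(c(p0, p1, q1, eta1, eta2), code_from_string, integer(1))
  structure(setNames(codes, QUANTITIES), class = "regulation_scheme")
}

#' @export
print.regulation_scheme <- function(x, ...) {
  cat("<regulation_scheme> ",
      paste(QUANTITIES, code_to_string(unclass(x)), sep = ":",
            collapse = " "), "\n")
  invisible(x)
}

#' The selected feedback-feedforward architecture
#'
#' Negative regulation of p0 by P, of p1 and q1 by TDm, and of eta1 and
#' eta2 by S (the last being the feedforward loop).
#' @return A [regulation_scheme()].
#' @export
fig2f_scheme <- function() {
  regulation_scheme(p0 = "P-", p1 = "TDm-", q1 = "TDm-",
                    eta1 = "S-", eta2 = "S-")
}

resolve_constraint <- function(x) {
  if (is.numeric(x)) {
    codes <- as.integer(x)
  } else if (identical(x, "negative")) {
    codes <- c(1L, 3L, 5L, 7L)
  } else if (identical(x, "positive")) {
    codes <- c(2L, 4L, 6L, 8L)
  } else {
    codes <- vapply(x, code_from_string, integer(1))
  }
  codes <- unique(codes)
  if (length(codes) == 0 || any(codes < 0L | codes > 8L))
    stop("contradictory or invalid constraint")
  sort(codes)
}

#' Enumerate regulation schemes
#'
#' @param constraints optional named list restricting quantities; each
#'   entry is `"negative"`, `"positive"`, a `"<cell><sign>"` / `"none"`
#'   string (or vector of them), or a vector of integer codes.
#' @return Integer matrix (one row per scheme, columns the five regulated
#'   quantities) with attribute `count`.
#' @export
enumerate_schemes <- function(constraints = NULL) {
  allowed <- rep(list(0:8), 5)
  names(allowed) <- QUANTITIES
  if (!is.null(constraints)) {
    bad <- setdiff(names(constraints), QUANTITIES)
    if (length(bad)) stop("unknown quantities: ", paste(bad, collapse = ", "))
    for (nm in names(constraints))
      allowed[[nm]] <- resolve_constraint(constraints[[nm]])
  }
  grid <- as.matrix(rev(expand.grid(rev(allowed), KEEP.OUT.ATTRS = FALSE)))
  storage.mode(grid) <- "integer"
  colnames(grid) <- QUANTITIES
  attr(grid, "count") <- nrow(grid)
  grid
}

# -- S-system construction (reference R implementation) ---------------------

# Parameter vector layout used throughout the design-space code:
# p0_max, p1_max, q1_max, eta1_max, eta2_max, d_l, d_m, and one gain per
# regulated quantity in quantity order (p0, p1, q1, eta1, eta2).
THETA_NAMES <- c("p0_max", "p1_max", "q1_max", "eta1_max", "eta2_max",
                 "d_l", "d_m", paste0("g_", QUANTITIES))

# Map a model parameter set (gamma1..gamma5 in the selected architecture)
# onto the design-space layout.
theta_from_params <- function(ps) {
  setNames(c(ps[["p0_max"]], ps[["p1_max"]], ps[["q1_max"]],
             ps[["eta1_max"]], ps[["eta2_max"]], ps[["d_l"]], ps[["d_m"]],
             ps[["gamma1"]], ps[["gamma3"]] / N0_CELLS,
             ps[["gamma4"]] / N0_CELLS, ps[["gamma2"]] / N0_CELLS,
             ps[["gamma5"]] / N0_CELLS), THETA_NAMES)
}

# Term representation: coef(theta) * exp(c0 + pw . log theta) * X^e, with
# composite coefficient codes 0:1, 1:(2 p0max - 1), 2:(1 - p0max),
# 3:|2 p1max - 1|, 4:(1 - p1max), 5:(1 - q1max), 6:(1 - p1max - q1max).
term <- function(c0 = 0, coef = 0L, pw = numeric(12), e = numeric(4)) {
  list(c0 = c0, coef = coef, pw = pw, e = e)
}
term_mul <- function(a, b) {
  stopifnot(a$coef == 0L || b$coef == 0L)
  term(a$c0 + b$c0, max(a$coef, b$coef), a$pw + b$pw, a$e + b$e)
}
# inequality / balance entry: log A - log B
expr_diff <- function(a, b) {
  list(c0 = a$c0 - b$c0, coefp = a$coef, coefm = b$coef,
       pw = a$pw - b$pw, e = a$e - b$e)
}
coef_logs <- function(theta) {
  p0 <- theta[1]; p1 <- theta[2]; q1 <- theta[3]
  log(c(1, 2 * p0 - 1, 1 - p0, abs(2 * p1 - 1), 1 - p1, 1 - q1,
        1 - p1 - q1))
}
term_logval <- function(t, lt, clog, y) {
  clog[t$coef + 1] + t$c0 + sum(t$pw * lt) + sum(t$e * y)
}
expr_val <- function(x, lt, clog, y) {
  clog[x$coefp + 1] - clog[x$coefm + 1] + x$c0 + sum(x$pw * lt) +
    sum(x$e * y)
}
gmono <- function(q, src) {
  term(pw = replace(numeric(12), 7 + q, 1),
       e = replace(numeric(4), src, 1))
}
dinv_mono <- function(q, src, branch) {
  if (branch == 0L) term() else
    term(pw = replace(numeric(12), 7 + q, -1),
         e = replace(numeric(4), src, -1))
}
mult_quantity <- function(q, code, branch) {
  t <- term(pw = replace(numeric(12), q, 1))
  if (code == 0L) return(t)
  src <- (code - 1L) %/% 2L + 1L
  if ((code - 1L) %% 2L == 1L) t <- term_mul(t, gmono(q, src))
  term_mul(t, dinv_mono(q, src, branch))
}

#' Decompose a scheme into its dominant power-law subsystems
#'
#' The four lineage ODEs are recast exactly as sums of signed power-law
#' terms: numerators of the composite factors `(2p0-1)`, `(1-p0)`,
#' `(2p1-1)` and `(1-p1-q1)` are expanded, every Hill denominator is
#' replaced by one of its two asymptotic branches (chosen globally per
#' regulated quantity), and the ambiguous sign of `(2 p1_max - 1)` is
#' enumerated as a sign regime. One S-system is emitted per combination
#' of branch assignment, sign regime, and choice of dominant source and
#' sink per equation; configurations in which some equation has no
#' source or no sink (and hence cannot balance) yield none.
#'
#' @param scheme a [regulation_scheme()].
#' @return List of S-system objects (`M`, log-linear balance, inequality
#'   set, branch assignment, sign regime, `singular` flag).
#' @export
build_ssystems <- function(scheme) {
  code <- as.integer(unclass(scheme))
  regq <- which(code != 0L)
  out <- list()
  for (p1hi in 0:1) for (mask in seq_len(2L^length(regq)) - 1L) {
    branch <- integer(5)
    if (length(regq))
      branch[regq] <- bitwAnd(bitwShiftR(mask, seq_along(regq) - 1L), 1L)
    sets <- ssystem_terms(code, branch, p1hi)
    if (is.null(sets)) next
    combos <- expand.grid(lapply(unlist(sets, recursive = FALSE),
                                 function(l) seq_along(l)))
    for (r in seq_len(nrow(combos))) {
      pick <- as.integer(combos[r, ])
      src <- lapply(1:4, function(i) sets$src[[i]][[pick[i]]])
      snk <- lapply(1:4, function(i) sets$snk[[i]][[pick[4 + i]]])
      M <- t(vapply(1:4, function(i) src[[i]]$e - snk[[i]]$e, numeric(4)))
      bal <- lapply(1:4, function(i) expr_diff(snk[[i]], src[[i]]))
      ineq <- list()
      for (i in 1:4) {
        for (k in seq_along(sets$src[[i]])) if (k != pick[i])
          ineq <- c(ineq, list(expr_diff(src[[i]], sets$src[[i]][[k]])))
        for (k in seq_along(sets$snk[[i]])) if (k != pick[4 + i])
          ineq <- c(ineq, list(expr_diff(snk[[i]], sets$snk[[i]][[k]])))
      }
      for (q in 1:5) {
        if (code[q] == 0L) next
        srcq <- (code[q] - 1L) %/% 2L + 1L
        sgn <- if (branch[q] == 1L) 1 else -1
        ineq <- c(ineq, list(list(
          c0 = 0, coefp = 0L, coefm = 0L,
          pw = replace(numeric(12), 7 + q, sgn),
          e = replace(numeric(4), srcq, sgn))))
      }
      sgn <- if (p1hi == 1L) 1 else -1
      ineq <- c(ineq, list(list(c0 = sgn * log(2), coefp = 0L, coefm = 0L,
                                pw = replace(numeric(12), 2, sgn),
                                e = numeric(4))))
      out[[length(out) + 1L]] <- structure(list(
        M = M, balance = bal, ineq = ineq, src = src, branch = branch,
        p1_high = p1hi == 1L, singular = abs(det(M)) < 1e-10),
        class = "ssystem")
    }
  }
  out
}

# Source and sink term lists per equation for one branch assignment and
# p1 sign regime; NULL when some equation cannot balance.
ssystem_terms <- function(code, branch, p1hi) {
  LOG2 <- log(2)
  s0 <- if (code[1]) (code[1] - 1L) %/% 2L + 1L else NA
  sg0 <- if (code[1]) (code[1] - 1L) %% 2L else NA
  s1 <- if (code[2]) (code[2] - 1L) %/% 2L + 1L else NA
  sg1 <- if (code[2]) (code[2] - 1L) %% 2L else NA
  s2 <- if (code[3]) (code[3] - 1L) %/% 2L + 1L else NA
  sg2 <- if (code[3]) (code[3] - 1L) %% 2L else NA
  e1S <- term_mul(mult_quantity(4, code[4], branch[4]),
                  term(e = c(1, 0, 0, 0)))
  e2P <- term_mul(mult_quantity(5, code[5], branch[5]),
                  term(e = c(0, 1, 0, 0)))
  d0i <- if (code[1]) dinv_mono(1, s0, branch[1]) else term()
  d1i <- if (code[2]) dinv_mono(2, s1, branch[2]) else term()
  d2i <- if (code[3]) dinv_mono(3, s2, branch[3]) else term()
  ct <- function(coef, c0 = 0) term(c0 = c0, coef = as.integer(coef))
  srcS <- snkS <- srcP <- snkP <- list()
  # S equation: (2 p0 - 1) eta1 S
  if (code[1] == 0L) {
    srcS <- list(term_mul(ct(1), e1S))
  } else if (sg0 == 0L) {
    srcS <- list(term_mul(term_mul(ct(1), e1S), d0i))
    snkS <- list(term_mul(term_mul(gmono(1, s0), e1S), d0i))
  } else {
    srcS <- list(term_mul(term_mul(term_mul(ct(1), gmono(1, s0)), e1S),
                          d0i))
    snkS <- list(term_mul(e1S, d0i))
  }
  # P equation: 2 (1 - p0) eta1 S + (2 p1 - 1) eta2 P
  if (code[1] == 0L) {
    srcP <- list(term_mul(ct(2, LOG2), e1S))
  } else if (sg0 == 0L) {
    srcP <- list(term_mul(term_mul(ct(2, LOG2), e1S), d0i),
                 term_mul(term_mul(term_mul(ct(0, LOG2), gmono(1, s0)),
                                   e1S), d0i))
  } else {
    srcP <- list(term_mul(term_mul(ct(0, LOG2), e1S), d0i),
                 term_mul(term_mul(term_mul(ct(2, LOG2), gmono(1, s0)),
                                   e1S), d0i))
  }
  if (code[2] == 0L) {
    t <- term_mul(ct(3), e2P)
    if (p1hi) srcP <- c(srcP, list(t)) else snkP <- c(snkP, list(t))
  } else if (sg1 == 0L) {
    t <- term_mul(term_mul(ct(3), e2P), d1i)
    if (p1hi) srcP <- c(srcP, list(t)) else snkP <- c(snkP, list(t))
    snkP <- c(snkP, list(term_mul(term_mul(gmono(2, s1), e2P), d1i)))
  } else {
    t <- term_mul(term_mul(term_mul(ct(3), gmono(2, s1)), e2P), d1i)
    if (p1hi) srcP <- c(srcP, list(t)) else snkP <- c(snkP, list(t))
    snkP <- c(snkP, list(term_mul(e2P, d1i)))
  }
  # TDl equation
  srcL <- list(term_mul(term_mul(ct(0, LOG2),
                                 mult_quantity(3, code[3], branch[3])),
                        e2P))
  snkL <- list(term(pw = replace(numeric(12), 6, 1),
                    e = c(0, 0, 1, 0)))
  # TDm equation: exact expansion of (1 - p1 - q1)
  g3 <- if (code[2]) gmono(2, s1) else NULL
  g4 <- if (code[3]) gmono(3, s2) else NULL
  c1m <- if (code[2] == 0L) 0L else if (sg1 == 0L) 1L else 2L
  c2m <- if (code[3] == 0L) 0L else if (sg2 == 0L) 1L else 2L
  num <- if (c1m == 0L && c2m == 0L) list(ct(6))
  else if (c1m == 0L && c2m == 1L) list(ct(6), term_mul(ct(4), g4))
  else if (c1m == 0L && c2m == 2L) list(ct(4), term_mul(ct(6), g4))
  else if (c1m == 1L && c2m == 0L) list(ct(6), term_mul(ct(5), g3))
  else if (c1m == 2L && c2m == 0L) list(ct(5), term_mul(ct(6), g3))
  else {
    cc <- if (c1m == 1L && c2m == 1L) c(6, 5, 4, 0)
    else if (c1m == 1L && c2m == 2L) c(4, 0, 6, 5)
    else if (c1m == 2L && c2m == 1L) c(5, 6, 0, 4)
    else c(0, 4, 5, 6)
    list(ct(cc[1]), term_mul(ct(cc[2]), g3), term_mul(ct(cc[3]), g4),
         term_mul(term_mul(ct(cc[4]), g3), g4))
  }
  srcM <- lapply(num, function(t)
    term_mul(term_mul(term_mul(term_mul(t, term(c0 = LOG2)), e2P), d1i),
             d2i))
  snkM <- list(term(pw = replace(numeric(12), 7, 1),
                    e = c(0, 0, 0, 1)))
  if (!length(srcS) || !length(snkS) || !length(srcP) || !length(snkP))
    return(NULL)
  list(src = list(srcS, srcP, srcL, srcM),
       snk = list(snkS, snkP, snkL, snkM))
}

#' Solve the log-linear equilibrium of an S-system
#'
#' @param ssys an S-system from [build_ssystems()].
#' @param theta parameter vector in design-space layout (see
#'   [theta_from_params()]), natural scale.
#' @return Named population vector, or `NULL` when the subsystem is
#'   singular or the equilibrium is out of numerical range.
#' @export
solve_ssystem <- function(ssys, theta) {
  if (ssys$singular) return(NULL)
  lt <- log(as.numeric(theta))
  clog <- coef_logs(as.numeric(theta))
  b <- vapply(ssys$balance, expr_val, numeric(1), lt = lt, clog = clog,
              y = numeric(4))
  if (any(!is.finite(b))) return(NULL)
  y <- tryCatch(solve(ssys$M, b), error = function(e) NULL)
  if (is.null(y) || any(!is.finite(y)) || any(abs(y) > 200)) return(NULL)
  setNames(exp(y), CELLS)
}

#' Self-consistency and stability of an S-system at its equilibrium
#'
#' Consistency: all dominance, Hill-regime and sign-regime inequalities
#' hold strictly at the equilibrium. Stability: all eigenvalues of the
#' subsystem Jacobian at the equilibrium have negative real part.
#'
#' @inheritParams solve_ssystem
#' @param eq equilibrium populations as returned by [solve_ssystem()].
#' @param margin strictness margin on log-scale inequalities; ties are
#'   treated as boundary and rejected.
#' @return Named logical vector `consistent, stable`.
#' @export
check_consistency_and_stability <- function(ssys, eq, theta,
                                            margin = 1e-9) {
  lt <- log(as.numeric(theta))
  clog <- coef_logs(as.numeric(theta))
  y <- log(as.numeric(eq))
  vals <- vapply(ssys$ineq, expr_val, numeric(1), lt = lt, clog = clog,
                 y = y)
  consistent <- all(vals > margin)
  w <- vapply(1:4, function(i)
    exp(term_logval(ssys$src[[i]], lt, clog, y) - y[i]), numeric(1))
  if (any(!is.finite(w))) return(c(consistent = FALSE, stable = FALSE))
  B <- diag(w) %*% ssys$M
  ev <- eigen(B, only.values = TRUE)$values
  stable <- all(Re(ev) < -1e-9 * max(Mod(ev)))
  c(consistent = consistent, stable = stable)
}

#' Broad parameter sample for design-space screening
#'
#' Fractions are drawn uniformly (p0_max on (0.5, 1); p1_max and q1_max
#' jointly so their sum stays below 1); rates and death rates
#' log-uniformly over four decades; gains log-uniformly over ten decades.
#' The sample is fixed by `seed` so screening verdicts are deterministic.
#'
#' @param n_samples number of parameter points.
#' @param seed RNG seed for the sample.
#' @return Matrix `n_samples x 12` of log-parameters (design-space layout).
#' @export
dsa_parameter_sample <- function(n_samples = 16, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  p0 <- runif(n_samples, 0.501, 0.999)
  p1 <- runif(n_samples, 0.05, 0.95)
  q1 <- runif(n_samples, 0.05, 0.95) * (1 - p1)
  rates <- function() 10^runif(n_samples, -3, 1)
  gains <- function() 10^runif(n_samples, -8, 2)
  m <- cbind(p0, p1, q1, rates(), rates(), rates(), rates(),
             gains(), gains(), gains(), gains(), gains())
  colnames(m) <- THETA_NAMES
  log(m)
}

# Establishment (boot-up) requirement: from a small stem-cell seed the S
# equation must have positive net growth in the small-population regime
# (all Hill denominators ~ 1), i.e. the lowest-degree S-equation term is
# a source. A positively regulated p0 has basal value below 1/2 and
# fails: such a lineage can never establish hematopoiesis.
establishment_ok <- function(scheme) {
  code <- as.integer(unclass(scheme))
  sets <- ssystem_terms(code, branch = integer(5), p1hi = 0L)
  if (is.null(sets))   # P equation lacks a sink; S terms still decisive
    sets <- list(src = list(ssystem_terms_s_only(code)$src),
                 snk = list(ssystem_terms_s_only(code)$snk))
  srcS <- sets$src[[1]]; snkS <- sets$snk[[1]]
  if (!length(snkS)) return(TRUE)
  deg <- function(l) min(vapply(l, function(t) sum(t$e), numeric(1)))
  deg(srcS) < deg(snkS)
}

# S-equation terms alone, low branches (helper for establishment_ok when
# the full term build bails out early).
ssystem_terms_s_only <- function(code) {
  e1S <- term_mul(mult_quantity(4, code[4], 0L), term(e = c(1, 0, 0, 0)))
  ct <- function(coef) term(coef = as.integer(coef))
  if (code[1] == 0L) return(list(src = list(term_mul(ct(1), e1S)),
                                 snk = list()))
  s0 <- (code[1] - 1L) %/% 2L + 1L
  if ((code[1] - 1L) %% 2L == 0L)
    list(src = list(term_mul(ct(1), e1S)),
         snk = list(term_mul(gmono(1, s0), e1S)))
  else
    list(src = list(term_mul(term_mul(ct(1), gmono(1, s0)), e1S)),
         snk = list(e1S))
}

# Pure-R scheme screen used as the independent cross-check of the
# compiled screen: same semantics, different code path.
screen_scheme_r <- function(scheme, logtheta, margin = 1e-9) {
  if (!establishment_ok(scheme))
    return(list(accepted = FALSE, n_surviving = 0L))
  sss <- build_ssystems(scheme)
  n_surv <- 0L
  for (ss in sss) {
    if (ss$singular) next
    for (k in seq_len(nrow(logtheta))) {
      theta <- exp(logtheta[k, ])
      eq <- solve_ssystem(ss, theta)
      if (is.null(eq)) next
      v <- check_consistency_and_stability(ss, eq, theta, margin)
      if (all(v)) { n_surv <- n_surv + 1L; break }
    }
  }
  list(accepted = n_surv > 0L, n_surviving = n_surv)
}

#' Screen schemes for viable, stable S-systems
#'
#' Runs the compiled screen over a set of schemes. A scheme is accepted
#' when it can establish hematopoiesis from a small stem-cell seed (see
#' the establishment requirement in [build_ssystems()] docs) and at least
#' one of its S-systems is self-consistent, stable, and has all four
#' populations positive, for at least one point of the parameter sample.
#' Accepted schemes are classified by the source of negative p0
#' regulation.
#'
#' @param schemes integer scheme matrix from [enumerate_schemes()] (or a
#'   single [regulation_scheme()]).
#' @param logtheta log-parameter sample from [dsa_parameter_sample()].
#' @param margin strictness margin for the inequalities.
#' @param count_surviving count every surviving S-system per scheme
#'   (`FALSE` stops at the first witness, which is faster for large
#'   enumerations).
#' @return List with `verdicts` (data frame: codes, accepted,
#'   n_surviving, class) and `class_summary` (accepted count per source of
#'   negative p0 regulation).
#' @export
filter_models <- function(schemes = enumerate_schemes(),
                          logtheta = dsa_parameter_sample(),
                          margin = 1e-9, count_surviving = TRUE) {
  if (inherits(schemes, "regulation_scheme"))
    schemes <- matrix(as.integer(unclass(schemes)), nrow = 1,
                      dimnames = list(NULL, QUANTITIES))
  res <- cpp_dsa_screen(schemes, logtheta, margin, count_surviving)
  cls <- rep(NA_character_, nrow(schemes))
  cls[res$p0_class > 0] <- CELLS[res$p0_class[res$p0_class > 0]]
  verdicts <- data.frame(
    scheme = apply(schemes, 1, function(r)
      paste(code_to_string(r), collapse = "/")),
    accepted = res$accepted, n_surviving = res$n_surviving,
    p0_negative_source = cls, stringsAsFactors = FALSE)
  class_summary <- table(verdicts$p0_negative_source[verdicts$accepted],
                         useNA = "ifany")
  list(verdicts = verdicts, class_summary = class_summary)
}

#' Map qualitative regions of the (gamma1, gamma3) plane
#'
#' For each grid point, the full model is integrated to steady state and
#' the point is labeled by which S-system of the selected architecture has
#' all dominance and regime conditions satisfied at that equilibrium
#' (`region = 0` when none strictly holds: a boundary point), and by the
#' eigenvalue type of the full-model Jacobian (node when all eigenvalues
#' are real, spiral otherwise).
#'
#' @param base_params a [normal_parameter_set()] providing all parameters
#'   except the swept gains.
#' @param gamma1_grid,gamma3_grid positive gain values to sweep.
#' @return Data frame `gamma1, gamma3, region, type`.
#' @export
map_design_space <- function(base_params, gamma1_grid, gamma3_grid) {
  stopifnot(all(gamma1_grid > 0), all(gamma3_grid > 0))
  sss <- build_ssystems(fig2f_scheme())
  grid <- expand.grid(gamma1 = gamma1_grid, gamma3 = gamma3_grid)
  region <- integer(nrow(grid)); type <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ps <- unclass(base_params)
    ps[["gamma1"]] <- grid$gamma1[i]
    ps[["gamma3"]] <- grid$gamma3[i]
    ps <- params_from_vector(ps)
    st <- find_steady_state(ps)
    if (!st$converged || any(st$state <= 0)) {
      region[i] <- NA_integer_; type[i] <- NA_character_; next
    }
    theta <- theta_from_params(ps)
    lt <- log(theta)
    clog <- coef_logs(theta)
    y <- log(st$state)
    hit <- 0L
    for (s in seq_along(sss)) {
      ss <- sss[[s]]
      if (ss$singular) next
      vals <- vapply(ss$ineq, expr_val, numeric(1), lt = lt, clog = clog,
                     y = y)
      if (all(vals > 0)) { hit <- s; break }
    }
    region[i] <- hit
    ev <- eigen(normal_jacobian(ps, st$state), only.values = TRUE)$values
    type[i] <- if (any(abs(Im(ev)) > 1e-10)) "spiral" else "node"
  }
  cbind(grid, region = region, type = type)
}
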