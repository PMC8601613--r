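#' @title Flux balance analysis and single-gene deletions
#'
#' @description
#' A constraint-based model is a stoichiometric matrix `S` (species by
#' reactions) with flux bounds and a linear objective (typically biomass
#' production); flux balance analysis maximizes the objective under the
#' steady-state constraint `S v = 0` and `lb <= v <= ub`. Gene deletion
#' sets the deleted gene to false in every GPR rule; reactions whose rule
#' evaluates false have their flux forced to zero (reactions with an empty
#' rule are never constrained), and the mutant is called viable when the
#' optimal biomass flux stays positive.
#'
#' @name fba
NULL

#' Construct a constraint-based model
#'
#' @param stoichiometry numeric matrix, species in rows, reactions in
#'   columns (column names are the reaction ids).
#' @param lb,ub numeric flux bounds per reaction (finite).
#' @param objective reaction id of the objective (biomass) reaction.
#' @param rules named list of `"gpr"` expressions or rule strings keyed by
#'   reaction id; reactions without an entry carry the empty rule.
#' @return An object of class `"fba_model"`.
#' @export
fba_model <- function(stoichiometry, lb, ub, objective, rules = list()) {
  stoichiometry <- as.matrix(stoichiometry)
  rxns <- colnames(stoichiometry)
  if (is.null(rxns)) stop("stoichiometry must have reaction column names")
  stopifnot(length(lb) == length(rxns), length(ub) == length(rxns),
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub),
            objective %in% rxns)
  rules <- lapply(rules, function(r) if (inherits(r, "gpr")) r else gpr_parse(r))
  unknown <- setdiff(names(rules), rxns)
  if (length(unknown))
    stop("rules reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  full <- stats::setNames(vector("list", length(rxns)), rxns)
  for (r in rxns) full[[r]] <- if (r %in% names(rules)) rules[[r]] else gpr_empty()
  structure(list(S = stoichiometry, lb = stats::setNames(lb, rxns),
                 ub = stats::setNames(ub, rxns), objective = objective,
                 rules = full),
            class = "fba_model")
}

#' @export
print.fba_model <- function(x, ...) {
  cat("<FBA model> ", nrow(x$S), " species x ", ncol(x$S),
      " reactions, objective ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Genes of an FBA model
#'
#' @param model an `"fba_model"`.
#' @return Sorted character vector of all genes appearing in the rules.
#' @export
fba_genes <- function(model) {
  sort(unique(unlist(lapply(model$rules, gpr_genes))))
}

## Two-phase primal simplex with Bland's anti-cycling rule for
##   max c'z  s.t.  A z = b, z >= 0
## Dense and deliberately simple: the deletion screens solve many small,
## highly degenerate LPs (whole pathways forced to zero), where pivoting
## must not cycle or run off the tableau. Returns status "optimal",
## "infeasible" or "unbounded".
lp_solve_eq <- function(A, b, cc, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  iterate <- function(Afull, b, cost, basis, allowed) {
    repeat {
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(NULL)
      xb <- as.numeric(Binv %*% b)
      y <- as.numeric(t(cost[basis]) %*% Binv)
      red <- cost - as.numeric(y %*% Afull)
      red[basis] <- 0
      ent <- which(red > tol & allowed)
      if (!length(ent))
        return(list(basis = basis, xb = xb,
                    value = sum(cost[basis] * xb)))
      j <- ent[1L]                       # Bland: smallest entering index
      d <- as.numeric(Binv %*% Afull[, j])
      pos <- which(d > tol)
      if (!length(pos)) return(list(unbounded = TRUE))
      ratios <- xb[pos] / d[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      leave <- cand[which.min(basis[cand])]  # Bland: smallest leaving index
      basis[leave] <- j
    }
  }

  Afull <- cbind(A, diag(m))
  art <- n + seq_len(m)
  # phase 1: drive the artificial variables to zero
  res1 <- iterate(Afull, b, cost = c(rep(0, n), rep(-1, m)),
                  basis = art, allowed = rep(TRUE, n + m))
  if (is.null(res1) || isTRUE(res1$unbounded) || res1$value < -tol)
    return(list(status = "infeasible"))
  basis <- res1$basis
  # pivot any zero-level artificial out of the basis where possible
  B <- Afull[, basis, drop = FALSE]
  Binv <- solve(B)
  drop_rows <- integer()
  for (r in which(basis > n)) {
    row <- as.numeric(Binv[r, , drop = FALSE] %*% Afull[, seq_len(n)])
    j <- which(abs(row) > tol)
    if (length(j)) {
      basis[r] <- j[1L]
      B <- Afull[, basis, drop = FALSE]
      Binv <- solve(B)
    } else {
      drop_rows <- c(drop_rows, r)      # redundant constraint
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    Afull <- Afull[keep, , drop = FALSE]
    b <- b[keep]
    basis <- basis[setdiff(seq_along(basis), drop_rows)]
  }
  # phase 2: original objective, artificials barred from entering
  res2 <- iterate(Afull, b, cost = c(cc, rep(0, m)), basis = basis,
                  allowed = c(rep(TRUE, n), rep(FALSE, m)))
  if (is.null(res2)) return(list(status = "infeasible"))
  if (isTRUE(res2$unbounded)) return(list(status = "unbounded"))
  z <- numeric(n + m)
  z[res2$basis] <- res2$xb
  list(status = "optimal", z = z[seq_len(n)], value = res2$value)
}

#' Maximize the model objective
#'
#' Solves the linear program `max c'v` subject to `S v = 0`,
#' `lb <= v <= ub` with a two-phase simplex using Bland's rule, after
#' substituting out fixed variables (knocked-out reactions). The solver
#' behind this function is a contract: any optimizer honouring bounds,
#' steady-state equalities and a linear objective is interchangeable
#' within tolerance.
#'
#' @param model an `"fba_model"`.
#' @param lb,ub optional bound overrides (named like the model bounds).
#' @return List with `feasible` (logical), `value` (objective optimum) and
#'   `fluxes` (named vector).
#' @export
optimize_flux <- function(model, lb = model$lb, ub = model$ub) {
  S <- model$S
  obj <- as.numeric(colnames(S) == model$objective)
  # fixed variables (lb == ub) are substituted out; free variables are
  # shifted to x = v - lb in [0, ub - lb], upper bounds become slack rows
  free <- (ub - lb) > 0
  rhs <- as.numeric(-S %*% lb)
  if (!any(free)) {
    feasible <- all(abs(rhs) < 1e-9)
    return(list(feasible = feasible,
                value = if (feasible) sum(obj * lb) else NA_real_,
                fluxes = if (feasible) stats::setNames(lb, colnames(S))
                         else NULL))
  }
  Sf <- S[, free, drop = FALSE]
  zero_row <- rowSums(Sf != 0) == 0L
  if (any(zero_row & abs(rhs) > 1e-9))
    return(list(feasible = FALSE, value = NA_real_, fluxes = NULL))
  Sf <- Sf[!zero_row, , drop = FALSE]
  rhs <- rhs[!zero_row]
  nf <- sum(free)
  u <- unname(ub - lb)[free]
  # standard form over [x, s]: Sf x = rhs ; x + s = u
  A <- rbind(cbind(Sf, matrix(0, nrow(Sf), nf)),
             cbind(diag(nf), diag(nf)))
  res <- lp_solve_eq(A, c(rhs, u), c(obj[free], rep(0, nf)))
  if (!identical(res$status, "optimal"))
    return(list(feasible = FALSE, value = NA_real_, fluxes = NULL))
  v <- lb
  v[free] <- res$z[seq_len(nf)] + lb[free]
  fluxes <- stats::setNames(v, colnames(S))
  list(feasible = TRUE, value = sum(obj * fluxes), fluxes = fluxes)
}

deletion_bounds <- function(model, genes) {
  lb <- model$lb; ub <- model$ub
  for (rid in names(model$rules)) {
    rule <- model$rules[[rid]]
    if (rule$kind == "EMPTY") next  # no-gene reactions are never knocked out
    g <- gpr_genes(rule)
    assign <- stats::setNames(!(g %in% genes), g)
    if (!gpr_evaluate(rule, assign)) {
      lb[rid] <- 0; ub[rid] <- 0
    }
  }
  list(lb = lb, ub = ub)
}

#' Viability of a gene-deletion mutant
#'
#' Deletes one or more genes, re-optimizes biomass, and calls the mutant
#' `viable` when the optimum exceeds the positivity tolerance, otherwise
#' `not_viable` (an infeasible mutant LP also counts as not viable). The
#' wild-type model must be feasible with positive biomass.
#'
#' @param model an `"fba_model"`.
#' @param genes gene identifier(s) to delete.
#' @param tol biomass-positivity tolerance (default `1e-9`).
#' @return `"viable"` or `"not_viable"`.
#' @export
gene_deletion_viability <- function(model, genes, tol = 1e-9) {
  wt <- optimize_flux(model)
  if (!wt$feasible || wt$value <= tol)
    stop("wild-type model is infeasible or has non-positive biomass",
         call. = FALSE)
  bounds <- deletion_bounds(model, genes)
  res <- optimize_flux(model, lb = bounds$lb, ub = bounds$ub)
  if (res$feasible && res$value > tol) "viable" else "not_viable"
}

#' Single-gene deletion screen
#'
#' @param model an `"fba_model"`.
#' @param genes genes to screen (default: all genes of the model rules).
#' @param tol biomass-positivity tolerance.
#' @return Data frame with columns `gene`, `predicted`.
#' @export
single_gene_deletions <- function(model, genes = fba_genes(model),
                                  tol = 1e-9) {
  wt <- optimize_flux(model)
  if (!wt$feasible || wt$value <= tol)
    stop("wild-type model is infeasible or has non-positive biomass",
         call. = FALSE)
  pred <- vapply(genes, function(g) {
    bounds <- deletion_bounds(model, g)
    res <- optimize_flux(model, lb = bounds$lb, ub = bounds$ub)
    if (res$feasible && res$value > tol) "viable" else "not_viable"
  }, character(1))
  data.frame(gene = genes, predicted = unname(pred), stringsAsFactors = FALSE)
}

#' Read / write a constraint-based model as a delimited table
#'
#' Plain-text FBA model format: one row per reaction with columns
#' `reaction_id`, `substrates`/`products` (pipe-separated
#' `species:coefficient` entries), `lb`, `ub`, `objective`
#' (`true`/`false`, exactly one row), `gpr` (rule string, possibly empty).
#'
#' @param path file path.
#' @return An `"fba_model"`.
#' @export
read_fba_model_tsv <- function(path) {
  raw <- read_tsv(path)
  for (col in c("reaction_id", "substrates", "products", "lb", "ub",
                "objective", "gpr")) {
    if (!col %in% names(raw))
      stop("FBA model table is missing required column '", col, "'",
           call. = FALSE)
  }
  subs <- split_side(raw$substrates)
  prods <- split_side(raw$products)
  species <- sort(unique(c(unlist(lapply(subs, `[[`, "compound")),
                           unlist(lapply(prods, `[[`, "compound")))))
  S <- matrix(0, nrow = length(species), ncol = nrow(raw),
              dimnames = list(species, raw$reaction_id))
  for (i in seq_len(nrow(raw))) {
    s <- subs[[i]]; p <- prods[[i]]
    if (nrow(s)) S[s$compound, i] <- S[s$compound, i] - s$coef
    if (nrow(p)) S[p$compound, i] <- S[p$compound, i] + p$coef
  }
  obj <- raw$reaction_id[raw$objective == "true"]
  if (length(obj) != 1L)
    stop("FBA model table must flag exactly one objective reaction",
         call. = FALSE)
  rules <- lapply(raw$gpr, gpr_parse)
  names(rules) <- raw$reaction_id
  fba_model(S, as.numeric(raw$lb), as.numeric(raw$ub), obj, rules)
}

#' @rdname read_fba_model_tsv
#' @param model an `"fba_model"`.
#' @return For the writer, `path` invisibly.
#' @export
write_fba_model_tsv <- function(model, path) {
  S <- model$S
  side_txt <- function(col, sign) {
    sel <- which(sign * S[, col] > 0)
    if (length(sel) == 0L) return("")
    paste(paste0(rownames(S)[sel], ":", format_coef(abs(S[sel, col]))),
          collapse = "|")
  }
  out <- data.frame(
    reaction_id = colnames(S),
    substrates = vapply(seq_len(ncol(S)), side_txt, character(1), sign = -1),
    products = vapply(seq_len(ncol(S)), side_txt, character(1), sign = 1),
    lb = format_coef(unname(model$lb)), ub = format_coef(unname(model$ub)),
    objective = tolower(colnames(S) == model$objective),
    gpr = vapply(model$rules[colnames(S)], gpr_serialize, character(1)),
    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

#' Confusion matrix of viability predictions
#'
#' Cross-tabulates predicted against annotated phenotype over
#' `{viable, not_viable}` and reports the proportion correct (trace over
#' total) plus the relative-frequency normalization of each cell.
#'
#' @param outcomes data frame with columns `gene`, `predicted`,
#'   `annotated` (values `"viable"`/`"not_viable"`; non-empty).
#' @return List of class `"gpr_confusion"` with `counts` (2x2 matrix,
#'   predicted in rows), `relative` (counts over total) and `accuracy`.
#' @export
confusion_matrix <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0L)
    stop("no outcomes to tabulate", call. = FALSE)
  lv <- c("viable", "not_viable")
  stopifnot(all(outcomes$predicted %in% lv), all(outcomes$annotated %in% lv))
  counts <- table(factor(outcomes$predicted, levels = lv),
                  factor(outcomes$annotated, levels = lv))
  counts <- unclass(counts)
  dimnames(counts) <- list(predicted = lv, annotated = lv)
  total <- sum(counts)
  structure(list(counts = counts, relative = counts / total,
                 accuracy = sum(diag(counts)) / total),
            class = "gpr_confusion")
}

#' @export
print.gpr_confusion <- function(x, ...) {
  cat("<confusion matrix> accuracy ", sprintf("%.3f", x$accuracy), "\n",
      sep = "")
  print(x$counts)
  invisible(x)
}
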