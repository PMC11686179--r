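## Minimal LP interface.
##
## Problems are built as plain lists (sparse triplets) and solved in batches by
## a helper script running scipy's HiGHS backend through the `python` on PATH
## (the only simplex implementation available in this stack). Only objective
## values cross the boundary: individual flux vectors are never reported,
## because the steady-state assumption admits multiple optimal solutions.

LP_INF <- 1e30

#' Construct an LP: maximize (or minimize) c'x s.t. Aeq x = beq, Aub x <= bub,
#' lb <= x <= ub
#'
#' @param c Objective coefficient vector (length n).
#' @param lb,ub Variable bounds; use `-Inf`/`Inf` for free variables.
#' @param Aeq,Aub Sparse triplet lists `list(i, j, v)` with 1-based indices,
#'   or `NULL`.
#' @param neq,nub Row counts of the two constraint blocks.
#' @param beq,bub Right-hand sides (`beq` defaults to zeros).
#' @param maximize Sense; default `TRUE`.
#' @return A list of class `lp_problem`.
#' @export
lp_problem <- function(c, lb, ub, Aeq = NULL, neq = 0L, beq = NULL,
                       Aub = NULL, nub = 0L, bub = NULL, maximize = TRUE) {
  lb[!is.finite(lb)] <- -LP_INF
  ub[!is.finite(ub)] <- LP_INF
  structure(list(c = as.numeric(c), lb = as.numeric(lb), ub = as.numeric(ub),
                 Aeq = Aeq, neq = as.integer(neq), beq = beq,
                 Aub = Aub, nub = as.integer(nub), bub = bub,
                 maximize = isTRUE(maximize)),
            class = "lp_problem")
}

lp_python <- function() {
  py <- getOption("babybiome.python", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found on PATH", call. = FALSE)
  py
}

#' Solve a batch of LPs
#'
#' @param problems A list of [lp_problem()] objects.
#' @return A list (same length) of `list(status, objective)`; `status` 0 means
#'   optimal, 2 infeasible, 3 unbounded; `objective` is `NA` unless optimal.
#' @export
solve_lp_batch <- function(problems) {
  if (length(problems) == 0L) return(list())
  strip <- function(p) {
    p <- unclass(p)
    if (is.null(p$Aeq)) p$neq <- 0L
    if (is.null(p$Aub)) p$nub <- 0L
    p <- p[!vapply(p, is.null, logical(1))]
    # keep vector fields as JSON arrays even at length 1
    for (f in intersect(c("c", "lb", "ub", "beq", "bub"), names(p))) {
      p[[f]] <- I(as.numeric(p[[f]]))
    }
    for (f in intersect(c("Aeq", "Aub"), names(p))) {
      p[[f]] <- lapply(p[[f]], function(v) I(as.numeric(v)))
    }
    p
  }
  payload <- list(problems = lapply(problems, strip))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "lp_batch.py", package = "babybiome")
  if (!nzchar(script)) {
    # during in-source development (pkgload), fall back to the source tree
    script <- file.path("inst", "python", "lp_batch.py")
  }
  status <- system2(lp_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(fout)) {
    stop("LP backend failed (python/scipy error)", call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)$results
  lapply(res, function(r) {
    list(status = r$status,
         objective = if (is.null(r$objective)) NA_real_ else r$objective)
  })
}

#' Solve a single LP
#' @param problem An [lp_problem()].
#' @return `list(status, objective)`.
#' @export
solve_lp <- function(problem) solve_lp_batch(list(problem))[[1]]

## ---- building LPs from models --------------------------------------------

# Steady-state triplets for a model: rows = metabolites (sorted), cols =
# reactions (model order). Returns list(Aeq, neq, met_index, rxn_index).
model_stoich_triplets <- function(model) {
  met_ids <- sort(model$mets$id)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  rxn_ids <- model$rxns$id
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$stoich[[rxn_ids[j]]]
    ii <- c(ii, unname(met_index[names(st)]))
    jj <- c(jj, rep.int(j, length(st)))
    vv <- c(vv, unname(st))
  }
  list(Aeq = list(i = ii, j = jj, v = vv), neq = length(met_ids),
       met_index = met_index,
       rxn_index = stats::setNames(seq_along(rxn_ids), rxn_ids))
}

# FBA problem over a plain model: maximize objective (named coefficients over
# reaction ids) subject to S v = 0 and the model bounds.
model_fba_problem <- function(model, objective, extra_ub = NULL) {
  tri <- model_stoich_triplets(model)
  n <- nrow(model$rxns)
  obj <- numeric(n)
  idx <- tri$rxn_index[names(objective)]
  if (anyNA(idx)) {
    stop(sprintf("objective names not in model: %s",
                 toString(names(objective)[is.na(idx)])), call. = FALSE)
  }
  obj[idx] <- as.numeric(objective)
  args <- list(c = obj, lb = model$rxns$lb, ub = model$rxns$ub,
               Aeq = tri$Aeq, neq = tri$neq, maximize = TRUE)
  if (!is.null(extra_ub)) {
    args$Aub <- extra_ub$A
    args$nub <- extra_ub$n
    args$bub <- extra_ub$b
  }
  do.call(lp_problem, args)
}

#' Maximal attainable flux for an objective on a single model
#'
#' Plain flux balance analysis: maximize a linear flux objective subject to
#' steady state and the model's bounds.
#'
#' @param model An `mbx_model`.
#' @param objective Named numeric vector of objective coefficients over
#'   reaction ids (e.g. `c(biomass = 1)`).
#' @return `list(status, objective)`.
#' @export
fba <- function(model, objective) {
  solve_lp(model_fba_problem(model, objective))
}
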