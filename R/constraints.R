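#' Parse a declarative structural constraint file
#'
#' One constraint per non-comment line, whitespace-delimited. Residues are
#' written `chain:resnum` and residue sets as comma-separated lists.
#' Supported forms:
#' \describe{
#'   \item{`contact A:176 B:164 4.5`}{minimum heavy-atom distance between
#'     the two residues is at most the cutoff (A).}
#'   \item{`interface_contains A B A:127,A:133,A:137`}{every listed residue
#'     loses accessible area in the A:B interface.}
#'   \item{`buried P:13 0.15`}{relative SASA of the residue in the whole
#'     assembly is at most the threshold.}
#'   \item{`accessible P:130 0.25`}{relative SASA is at least the
#'     threshold.}
#'   \item{`disjoint_interfaces A:10,A:11 A:20,A:24`}{the two residue sets
#'     share no residue.}
#'   \item{`symmetric A B 0.5`}{the two chains form a two-fold symmetric
#'     pair within the given RMSD (A).}
#' }
#' An optional trailing `# comment` per line is kept as the constraint
#' label.
#'
#' @param path file to read.
#' @return An object of class `constraint_set` (a list of typed records).
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  recs <- list()
  for (ln in lines) {
    label <- ""
    if (grepl("#", ln, fixed = TRUE)) {
      label <- trimws(sub("^[^#]*#", "", ln))
      ln <- sub("#.*$", "", ln)
    }
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    recs[[length(recs) + 1L]] <- parse_constraint(tok, label)
  }
  structure(recs, class = "constraint_set")
}

#' Build a constraint set programmatically
#'
#' @param ... constraint records as returned by [constraint()].
#' @return A `constraint_set`.
#' @export
constraint_set <- function(...) {
  recs <- list(...)
  stopifnot(all(vapply(recs, inherits, logical(1), "assocfit_constraint")))
  structure(recs, class = "constraint_set")
}

#' Build one typed constraint record
#'
#' See [read_constraints()] for the semantics of each type.
#'
#' @param type one of `contact`, `interface_contains`, `buried`,
#'   `accessible`, `disjoint_interfaces`, `symmetric`.
#' @param ... type-specific fields (`res`, `resA`, `resB`, `chainA`,
#'   `chainB`, `residues`, `set1`, `set2`, `cutoff`, `max_rel`, `min_rel`,
#'   `max_rmsd`).
#' @param label optional human-readable label.
#' @return A constraint record.
#' @export
constraint <- function(type, ..., label = "") {
  structure(c(list(type = type, label = label), list(...)),
            class = "assocfit_constraint")
}

parse_constraint <- function(tok, label = "") {
  type <- tok[1L]
  switch(type,
    contact = {
      stopifnot(length(tok) == 4L)
      constraint("contact", resA = tok[2L], resB = tok[3L],
                 cutoff = as.numeric(tok[4L]), label = label)
    },
    interface_contains = {
      stopifnot(length(tok) == 4L)
      constraint("interface_contains", chainA = tok[2L], chainB = tok[3L],
                 residues = strsplit(tok[4L], ",")[[1L]], label = label)
    },
    buried = {
      stopifnot(length(tok) == 3L)
      constraint("buried", res = tok[2L], max_rel = as.numeric(tok[3L]),
                 label = label)
    },
    accessible = {
      stopifnot(length(tok) == 3L)
      constraint("accessible", res = tok[2L], min_rel = as.numeric(tok[3L]),
                 label = label)
    },
    disjoint_interfaces = {
      stopifnot(length(tok) == 3L)
      constraint("disjoint_interfaces",
                 set1 = strsplit(tok[2L], ",")[[1L]],
                 set2 = strsplit(tok[3L], ",")[[1L]], label = label)
    },
    symmetric = {
      stopifnot(length(tok) == 4L)
      constraint("symmetric", chainA = tok[2L], chainB = tok[3L],
                 max_rmsd = as.numeric(tok[4L]), label = label)
    },
    stop("unknown constraint type: ", type))
}

residue_exists <- function(model, ref) {
  p <- parse_resref(ref)
  any(model$atoms$chain == p$chain & model$atoms$resno == p$resno &
        model$atoms$insert == p$insert)
}

min_residue_distance <- function(model, refA, refB) {
  pa <- parse_resref(refA); pb <- parse_resref(refB)
  a <- heavy_atoms(model$atoms[model$atoms$chain == pa$chain &
                                 model$atoms$resno == pa$resno, , drop = FALSE])
  b <- heavy_atoms(model$atoms[model$atoms$chain == pb$chain &
                                 model$atoms$resno == pb$resno, , drop = FALSE])
  min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
             outer(a$z, b$z, "-")^2))
}

## Evaluate one constraint; returns list(status, value, margin, detail).
eval_constraint <- function(con, model, sasa_cache) {
  unev <- function(reason) list(status = "unevaluable", value = NA_real_,
                                margin = NA_real_, detail = reason)
  switch(con$type,
    contact = {
      for (ref in c(con$resA, con$resB))
        if (!residue_exists(model, ref))
          return(unev(paste("residue absent:", ref)))
      d <- min_residue_distance(model, con$resA, con$resB)
      list(status = if (d <= con$cutoff) "pass" else "fail",
           value = d, margin = con$cutoff - d,
           detail = sprintf("min distance %.2f A vs cutoff %.2f A",
                            d, con$cutoff))
    },
    interface_contains = {
      chains <- unique(model$atoms$chain)
      if (!all(c(con$chainA, con$chainB) %in% chains))
        return(unev("interface chain absent"))
      for (ref in con$residues)
        if (!residue_exists(model, ref))
          return(unev(paste("residue absent:", ref)))
      rep_ <- interface_cached(model, con$chainA, con$chainB, sasa_cache)
      dl <- rep_$delta_sasa[con$residues]
      if (anyNA(dl))
        return(unev("residue not in interface chains"))
      list(status = if (all(dl > 1e-6)) "pass" else "fail",
           value = min(dl), margin = min(dl),
           detail = sprintf("min delta-SASA %.2f A^2 over %d residues",
                            min(dl), length(dl)))
    },
    buried = {
      if (!residue_exists(model, con$res))
        return(unev(paste("residue absent:", con$res)))
      rel <- rel_sasa_cached(model, sasa_cache)[con$res]
      if (is.na(rel)) return(unev("no reference area for residue type"))
      list(status = if (rel <= con$max_rel) "pass" else "fail",
           value = unname(rel), margin = con$max_rel - unname(rel),
           detail = sprintf("relative SASA %.3f vs max %.3f",
                            rel, con$max_rel))
    },
    accessible = {
      if (!residue_exists(model, con$res))
        return(unev(paste("residue absent:", con$res)))
      rel <- rel_sasa_cached(model, sasa_cache)[con$res]
      if (is.na(rel)) return(unev("no reference area for residue type"))
      list(status = if (rel >= con$min_rel) "pass" else "fail",
           value = unname(rel), margin = unname(rel) - con$min_rel,
           detail = sprintf("relative SASA %.3f vs min %.3f",
                            rel, con$min_rel))
    },
    disjoint_interfaces = {
      for (ref in c(con$set1, con$set2))
        if (!residue_exists(model, ref))
          return(unev(paste("residue absent:", ref)))
      shared <- intersect(con$set1, con$set2)
      cross <- min(vapply(con$set1, function(a)
        min(vapply(con$set2, function(b)
          min_residue_distance(model, a, b), numeric(1))), numeric(1)))
      list(status = if (length(shared) == 0L) "pass" else "fail",
           value = length(shared), margin = cross,
           detail = if (length(shared)) paste("shared residues:",
                                              paste(shared, collapse = ","))
                    else sprintf("disjoint; min cross distance %.1f A", cross))
    },
    symmetric = {
      chains <- unique(model$atoms$chain)
      if (!all(c(con$chainA, con$chainB) %in% chains))
        return(unev("chain absent"))
      rmsd <- tryCatch(c2_symmetry_rmsd(model, con$chainA, con$chainB),
                       error = function(e) NA_real_)
      if (is.na(rmsd)) return(unev("chains not matchable atom-by-atom"))
      list(status = if (rmsd <= con$max_rmsd) "pass" else "fail",
           value = rmsd, margin = con$max_rmsd - rmsd,
           detail = sprintf("two-fold RMSD %.3f A vs max %.3f A",
                            rmsd, con$max_rmsd))
    },
    unev(paste("unknown constraint type:", con$type)))
}

interface_cached <- function(model, chainA, chainB, cache) {
  key <- paste0("iface:", chainA, ":", chainB)
  if (is.null(cache[[key]]))
    cache[[key]] <- interface_area(model, chainA, chainB)
  cache[[key]]
}

rel_sasa_cached <- function(model, cache) {
  if (is.null(cache[["rel_all"]]))
    cache[["rel_all"]] <- relative_sasa(sasa(model))
  cache[["rel_all"]]
}

#' Audit a structure against a declarative constraint set
#'
#' Evaluates every constraint independently against the model; a constraint
#' that references an absent residue or chain is reported as unevaluable
#' rather than failed. The report is deterministic and each row is
#' independent of the order of the constraints.
#'
#' @param model a [structure_model()].
#' @param constraints a `constraint_set` from [read_constraints()] or
#'   [constraint_set()].
#' @return An object of class `constraint_report`: a data frame with one
#'   row per constraint (`type`, `label`, `status`, `value`, `margin`,
#'   `detail`) plus an `overall_pass` attribute (TRUE when no constraint
#'   failed; unevaluable constraints do not count as failures).
#' @export
audit_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "structure_model"),
            inherits(constraints, "constraint_set"))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(constraints, function(con) {
    ev <- eval_constraint(con, model, cache)
    data.frame(type = con$type, label = con$label, status = ev$status,
               value = ev$value, margin = ev$margin, detail = ev$detail,
               stringsAsFactors = FALSE)
  })
  rep_ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), label = character(0),
               status = character(0), value = numeric(0),
               margin = numeric(0), detail = character(0))
  attr(rep_, "overall_pass") <- !any(rep_$status == "fail")
  class(rep_) <- c("constraint_report", "data.frame")
  rep_
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("Constraint audit: %d constraints, %d pass, %d fail, %d unevaluable\n",
              nrow(x), sum(x$status == "pass"), sum(x$status == "fail"),
              sum(x$status == "unevaluable")))
  if (nrow(x)) print.data.frame(x)
  cat("overall:", if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  invisible(x)
}
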