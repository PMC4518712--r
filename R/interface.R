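#' Buried interface area and residue classes between two chains
#'
#' Quantifies a two-chain interface from surface areas:
#' \deqn{A_{buried} = (SASA_A + SASA_B - SASA_{AB}) / 2}
#' per monomer. Residues touched by the interface (positive SASA change on
#' complexation) are classified core or rim by relative accessibility:
#' a residue is *core* when it is essentially buried in the complex
#' (relative SASA < `core_rel_cut`) while accessible in the free monomer
#' (relative SASA >= `core_rel_cut`); every other touched residue is *rim*.
#' Relative SASA is the residue SASA divided by its extended-state
#' reference area.
#'
#' @param model a [structure_model()] containing both chains.
#' @param chainA,chainB chain identifiers.
#' @param probe,n_points,radii_set,radii_override,unknown_radius passed to
#'   [sasa()].
#' @param core_rel_cut relative-SASA threshold for the core class
#'   (default 0.07).
#' @param contact_cutoff heavy-atom distance (A) defining contact pairs.
#' @return An object of class `interface_report` with `buried_per_monomer`
#'   (A^2), `residue_classes` (named character vector over both chains'
#'   residues: "core", "rim" or "none"), `delta_sasa` (per residue, A^2),
#'   `contact_pairs` (data frame of residue pairs within the cutoff) and
#'   the per-state SASA totals.
#' @export
interface_area <- function(model, chainA, chainB, probe = 1.4,
                           n_points = 960L, radii_set = "protor",
                           radii_override = numeric(0), unknown_radius = 1.8,
                           core_rel_cut = 0.07, contact_cutoff = 4.5) {
  chains <- unique(model$atoms$chain)
  if (!chainA %in% chains) stop("chain not present: ", chainA)
  if (!chainB %in% chains) stop("chain not present: ", chainB)
  sub <- structure_model(model$atoms[model$atoms$chain %in% c(chainA, chainB),
                                     , drop = FALSE])
  sA <- sasa(subset_chains(sub, chainA), probe, n_points, radii_set,
             radii_override, unknown_radius)
  sB <- sasa(subset_chains(sub, chainB), probe, n_points, radii_set,
             radii_override, unknown_radius)
  sAB <- sasa(sub, probe, n_points, radii_set, radii_override, unknown_radius)
  buried <- max((sA$total + sB$total - sAB$total) / 2, 0)

  free_res <- c(sA$per_residue, sB$per_residue)
  complex_res <- sAB$per_residue[names(free_res)]
  delta <- as.numeric(free_res) - as.numeric(complex_res)
  names(delta) <- names(free_res)

  rel_free <- c(relative_sasa(sA), relative_sasa(sB))[names(free_res)]
  rel_complex <- relative_sasa(sAB)[names(free_res)]
  classes <- rep("none", length(free_res))
  names(classes) <- names(free_res)
  touched <- delta > 1e-6 & buried > 0
  is_core <- touched & !is.na(rel_complex) & !is.na(rel_free) &
    rel_complex < core_rel_cut & rel_free >= core_rel_cut
  classes[touched] <- "rim"
  classes[is_core] <- "core"

  structure(list(buried_per_monomer = buried,
                 residue_classes = classes,
                 delta_sasa = delta,
                 rel_sasa_free = rel_free, rel_sasa_complex = rel_complex,
                 contact_pairs = interface_contact_pairs(sub, chainA, chainB,
                                                         contact_cutoff),
                 sasa_A = sA$total, sasa_B = sB$total, sasa_AB = sAB$total,
                 chainA = chainA, chainB = chainB),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface %s:%s\n", x$chainA, x$chainB))
  cat(sprintf("  buried area per monomer = %.1f A^2\n", x$buried_per_monomer))
  cat(sprintf("  free-chain SASA: %s %.1f, %s %.1f A^2; complex %.1f A^2\n",
              x$chainA, x$sasa_A, x$chainB, x$sasa_B, x$sasa_AB))
  tab <- table(factor(x$residue_classes, c("core", "rim", "none")))
  cat(sprintf("  residue classes: %d core, %d rim, %d untouched\n",
              tab["core"], tab["rim"], tab["none"]))
  cat(sprintf("  %d residue contact pairs within cutoff\n",
              nrow(x$contact_pairs)))
  invisible(x)
}

## All cross-chain residue pairs with any heavy-atom distance <= cutoff.
interface_contact_pairs <- function(model, chainA, chainB, cutoff = 4.5) {
  a <- heavy_atoms(model$atoms[model$atoms$chain == chainA, , drop = FALSE])
  b <- heavy_atoms(model$atoms[model$atoms$chain == chainB, , drop = FALSE])
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(resA = character(0), resB = character(0),
                      min_dist = numeric(0)))
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
              outer(a$z, b$z, "-")^2)
  ka <- residue_key(a); kb <- residue_key(b)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(resA = character(0), resB = character(0),
                      min_dist = numeric(0)))
  pair <- paste(ka[hit[, 1L]], kb[hit[, 2L]], sep = "|")
  mind <- tapply(d[hit], pair, min)
  parts <- strsplit(names(mind), "|", fixed = TRUE)
  out <- data.frame(resA = vapply(parts, `[`, "", 1L),
                    resB = vapply(parts, `[`, "", 2L),
                    min_dist = as.numeric(mind))
  out[order(out$resA, out$resB), , drop = FALSE]
}

#' Residues of partner chains contacting a given residue
#'
#' @param model a [structure_model()].
#' @param chain chain of the query residue.
#' @param resno author residue number of the query residue.
#' @param cutoff heavy-atom distance cutoff, angstrom; a pair at exactly the
#'   cutoff counts as a contact.
#' @param partner_chains chains to search (default: all chains except
#'   `chain`).
#' @return Data frame with columns `chain`, `resno`, `resid`, `min_dist`,
#'   one row per contacting residue, sorted by chain then residue number.
#' @export
contact_residues <- function(model, chain, resno, cutoff = 4.5,
                             partner_chains = NULL) {
  sel <- model$atoms$chain == chain & model$atoms$resno == resno
  if (!any(sel)) stop("residue not found: ", chain, ":", resno)
  q <- heavy_atoms(model$atoms[sel, , drop = FALSE])
  if (is.null(partner_chains))
    partner_chains <- setdiff(unique(model$atoms$chain), chain)
  p <- heavy_atoms(model$atoms[model$atoms$chain %in% partner_chains,
                               , drop = FALSE])
  if (nrow(p) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  d <- sqrt(outer(q$x, p$x, "-")^2 + outer(q$y, p$y, "-")^2 +
              outer(q$z, p$z, "-")^2)
  mind <- apply(d, 2L, min)
  kp <- paste(p$chain, p$resno, sep = "\r")
  res_min <- tapply(mind, kp, min)
  keep <- res_min <= cutoff
  if (!any(keep))
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  first <- !duplicated(kp)
  info <- data.frame(key = kp[first], chain = p$chain[first],
                     resno = p$resno[first], resid = p$resid[first])
  info <- info[match(names(res_min)[keep], info$key), , drop = FALSE]
  out <- data.frame(chain = info$chain, resno = info$resno,
                    resid = info$resid,
                    min_dist = as.numeric(res_min[keep]))
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linker-reach feasibility between two anchor points
#'
#' A disordered linker of `n_linker_residues` residues can span at most
#' `n * d_max` angstrom between its anchoring atoms (default
#' `d_max = 3.8` A, the Calpha-Calpha virtual bond length, an upper bound
#' on per-residue extension; 3.63 A, the trans-peptide contour length per
#' residue, is the common alternative). The interaction is feasible in cis
#' when the anchor separation does not exceed the maximal reach.
#'
#' @param anchor1,anchor2 length-3 numeric coordinates (angstrom).
#' @param n_linker_residues number of linker residues (>= 0).
#' @param d_max maximal extension per residue, angstrom.
#' @return An object of class `linker_check` with `anchor_distance`,
#'   `max_reach`, `feasible` and `margin` (= max reach - distance; negative
#'   when infeasible).
#' @export
linker_feasible <- function(anchor1, anchor2, n_linker_residues,
                            d_max = 3.8) {
  if (n_linker_residues < 0) stop("n_linker_residues must be >= 0")
  stopifnot(length(anchor1) == 3L, length(anchor2) == 3L)
  dist <- sqrt(sum((as.numeric(anchor1) - as.numeric(anchor2))^2))
  reach <- n_linker_residues * d_max
  structure(list(n_linker_residues = n_linker_residues,
                 anchor_distance = dist,
                 max_extension_per_residue = d_max,
                 max_reach = reach,
                 feasible = dist <= reach,
                 margin = reach - dist),
            class = "linker_check")
}

#' @export
print.linker_check <- function(x, ...) {
  cat(sprintf(
    "Linker check: %d residues x %.2f A = %.1f A reach; anchors %.1f A apart -> %s (margin %.1f A)\n",
    x$n_linker_residues, x$max_extension_per_residue, x$max_reach,
    x$anchor_distance, if (x$feasible) "feasible" else "infeasible",
    x$margin))
  invisible(x)
}

## Kabsch superposition: rotation R and translation t minimising
## || Q - (P R + t) ||; returns the transform and the post-fit RMSD.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cq - drop(cp %*% R)
  fitted <- P %*% R + matrix(t_vec, nrow(P), 3L, byrow = TRUE)
  list(R = R, t = t_vec, rmsd = sqrt(mean(rowSums((Q - fitted)^2))),
       apply = function(X) X %*% R + matrix(t_vec, nrow(X), 3L, byrow = TRUE))
}

## Two-fold (C2) symmetry deviation between two chains: superpose A onto B
## (atoms paired by residue number + atom name), then apply the same
## transform to B; for a true two-fold the transform is an involution and
## maps B back onto A. Returns the RMSD of that round trip.
c2_symmetry_rmsd <- function(model, chainA, chainB) {
  a <- heavy_atoms(model$atoms[model$atoms$chain == chainA, , drop = FALSE])
  b <- heavy_atoms(model$atoms[model$atoms$chain == chainB, , drop = FALSE])
  ka <- paste(a$resno, a$insert, a$elety)
  kb <- paste(b$resno, b$insert, b$elety)
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stop("chains ", chainA, " and ", chainB,
         " share fewer than 3 matchable atoms")
  P <- as.matrix(a[match(common, ka), c("x", "y", "z")])
  Q <- as.matrix(b[match(common, kb), c("x", "y", "z")])
  fit <- kabsch(P, Q)          # A -> B
  back <- fit$apply(Q)         # apply again to B; C2 => back on A
  sqrt(mean(rowSums((back - P)^2)))
}
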