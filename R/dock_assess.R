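# CAPRI-style assessment of docking models against a reference
# complex: native-contact fraction, rigid-body superposition, ligand
# and interface RMSDs, and the four-class quality call.

# Single source of truth for the published CAPRI conventions.
.CAPRI <- list(
  contact_cutoff = 5,       # A, any heavy-atom pair
  interface_cutoff = 10,    # A, residues defining the interface for i-RMSD
  backbone = c("N", "CA", "C", "O"),
  high       = list(fnat = 0.5, lrmsd = 1,  irmsd = 1),
  medium     = list(fnat = 0.3, lrmsd = 5,  irmsd = 2),
  acceptable = list(fnat = 0.1, lrmsd = 10, irmsd = 4)
)

.heavy_atoms <- function(model, chains) {
  at <- model$atoms
  at[at$chain %in% chains & at$element != "H", , drop = FALSE]
}

# residue pairs with any atom-atom distance <= cutoff
.residue_contacts <- function(rec, lig, cutoff) {
  if (!nrow(rec) || !nrow(lig)) stop("empty chains in contact computation")
  rc <- as.matrix(rec[, c("x", "y", "z")])
  lc <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(rc^2), rowSums(lc^2), "+") - 2 * rc %*% t(lc)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(rec_chain = character(0), rec_resno = integer(0),
                      lig_chain = character(0), lig_resno = integer(0),
                      stringsAsFactors = FALSE))
  out <- unique(data.frame(
    rec_chain = rec$chain[hit[, 1]], rec_resno = rec$resno[hit[, 1]],
    lig_chain = lig$chain[hit[, 2]], lig_resno = lig$resno[hit[, 2]],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Native contacts of a two-partner complex
#'
#' All (receptor residue, ligand residue) pairs with any heavy-atom
#' pair within the contact cutoff (5 A, the CAPRI convention).
#'
#' @param model A [structure_model()] holding both partners.
#' @param receptor_chains,ligand_chain Chain identifiers of the two
#'   partners.
#' @param cutoff Contact cutoff, A.
#' @return Data frame of contacting residue pairs.
#' @export
native_contacts <- function(model, receptor_chains, ligand_chain,
                            cutoff = .CAPRI$contact_cutoff) {
  .residue_contacts(.heavy_atoms(model, receptor_chains),
                    .heavy_atoms(model, ligand_chain), cutoff)
}

#' Fraction of native contacts reproduced by a model
#'
#' @param model,reference [structure_model()]s with corresponding
#'   chains and residue numbering.
#' @param receptor_chains,ligand_chain Partner chain identifiers.
#' @param cutoff Contact cutoff, A.
#' @return `|model contacts intersect reference contacts| / |reference
#'   contacts|`.
#' @export
fnat <- function(model, reference, receptor_chains, ligand_chain,
                 cutoff = .CAPRI$contact_cutoff) {
  ref <- native_contacts(reference, receptor_chains, ligand_chain, cutoff)
  if (!nrow(ref)) stop("reference complex has no contacts; fnat undefined")
  mod <- native_contacts(model, receptor_chains, ligand_chain, cutoff)
  keys <- function(d) paste(d$rec_chain, d$rec_resno, d$lig_chain, d$lig_resno)
  length(intersect(keys(mod), keys(ref))) / nrow(ref)
}

#' Optimal rigid-body superposition (least squares)
#'
#' Closed-form solution via the covariance/SVD construction with a
#' proper rotation enforced (det = +1).
#'
#' @param mobile,target n x 3 coordinate matrices of paired points,
#'   n >= 3 and non-degenerate.
#' @return A list with `rotation` (3 x 3), the centroids, `rmsd` after
#'   superposition, and `transform(x)` applying the fit to new
#'   coordinates.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3L)
    stop("superpose needs equal-length n x 3 coordinate sets")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(t(A) %*% B)
  if (s$d[2] < 1e-8) stop("degenerate (collinear) geometry in superposition")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  transform <- function(x) {
    sweep(sweep(as.matrix(x), 2, cm) %*% t(R), 2, ct, `+`)
  }
  list(rotation = R, center_mobile = cm, center_target = ct,
       rmsd = rmsd, transform = transform)
}

# paired backbone coordinates between two models, matched by
# (chain, resno, atom); missing atoms are dropped pairwise
.paired_backbone <- function(model, reference, chains,
                             resnos = NULL, warn = TRUE) {
  pick <- function(m) {
    at <- m$atoms
    sel <- at$chain %in% chains & at$atom %in% .CAPRI$backbone
    if (!is.null(resnos))
      sel <- sel & paste(at$chain, at$resno) %in% resnos
    at[sel, , drop = FALSE]
  }
  am <- pick(model); ar <- pick(reference)
  km <- paste(am$chain, am$resno, am$atom)
  kr <- paste(ar$chain, ar$resno, ar$atom)
  common <- intersect(km, kr)
  if (warn && (length(common) < length(km) || length(common) < length(kr)))
    warning("dropping ", length(km) + length(kr) - 2 * length(common),
            " unpaired backbone atoms")
  if (!length(common))
    stop("no paired backbone atoms between model and reference")
  list(model = as.matrix(am[match(common, km), c("x", "y", "z")]),
       reference = as.matrix(ar[match(common, kr), c("x", "y", "z")]))
}

#' Ligand RMSD of a docking model
#'
#' The model is superposed on the reference over the receptor backbone;
#' the RMSD is then computed over the ligand backbone without further
#' fitting, so it measures the ligand's placement error.
#'
#' @inheritParams fnat
#' @return RMSD in A.
#' @export
ligand_rmsd <- function(model, reference, receptor_chains, ligand_chain) {
  rec <- .paired_backbone(model, reference, receptor_chains)
  fit <- superpose(rec$model, rec$reference)
  lig <- .paired_backbone(model, reference, ligand_chain)
  moved <- fit$transform(lig$model)
  sqrt(mean(rowSums((moved - lig$reference)^2)))
}

#' Interface RMSD of a docking model
#'
#' Backbone RMSD over the reference interface residues (any residue
#' with a heavy atom within 10 A of the partner), after superposing on
#' those same atoms - the CAPRI i-RMSD.
#'
#' @inheritParams fnat
#' @return RMSD in A.
#' @export
interface_rmsd <- function(model, reference, receptor_chains, ligand_chain) {
  ic <- .residue_contacts(.heavy_atoms(reference, receptor_chains),
                          .heavy_atoms(reference, ligand_chain),
                          .CAPRI$interface_cutoff)
  resnos <- unique(c(paste(ic$rec_chain, ic$rec_resno),
                     paste(ic$lig_chain, ic$lig_resno)))
  pb <- .paired_backbone(model, reference,
                         c(receptor_chains, ligand_chain), resnos)
  superpose(pb$model, pb$reference)$rmsd
}

#' CAPRI quality class
#'
#' Standard CAPRI thresholds: high if fnat >= 0.5 and (L-RMSD <= 1 or
#' i-RMSD <= 1); else medium if fnat >= 0.3 and (L-RMSD <= 5 or
#' i-RMSD <= 2); else acceptable if fnat >= 0.1 and (L-RMSD <= 10 or
#' i-RMSD <= 4); else incorrect.
#'
#' @param fnat Fraction of native contacts, in \[0, 1\].
#' @param ligand_rmsd,interface_rmsd RMSDs in A.
#' @return One of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
#' @examples
#' capri_class(0.60, 5.2, 3)  # "acceptable"
capri_class <- function(fnat, ligand_rmsd, interface_rmsd) {
  stopifnot(is.finite(fnat), is.finite(ligand_rmsd), is.finite(interface_rmsd))
  cl <- .CAPRI
  if (fnat >= cl$high$fnat &&
      (ligand_rmsd <= cl$high$lrmsd || interface_rmsd <= cl$high$irmsd))
    return("high")
  if (fnat >= cl$medium$fnat &&
      (ligand_rmsd <= cl$medium$lrmsd || interface_rmsd <= cl$medium$irmsd))
    return("medium")
  if (fnat >= cl$acceptable$fnat &&
      (ligand_rmsd <= cl$acceptable$lrmsd || interface_rmsd <= cl$acceptable$irmsd))
    return("acceptable")
  "incorrect"
}

#' Assess one docking model against a reference complex
#'
#' @inheritParams fnat
#' @param model_id Identifier carried into the result.
#' @return One-row data frame: `model_id`, `fnat`, `ligand_rmsd`,
#'   `interface_rmsd`, `quality`.
#' @export
assess_model <- function(model, reference, receptor_chains, ligand_chain,
                         model_id = "model") {
  fn <- fnat(model, reference, receptor_chains, ligand_chain)
  lr <- ligand_rmsd(model, reference, receptor_chains, ligand_chain)
  ir <- interface_rmsd(model, reference, receptor_chains, ligand_chain)
  data.frame(model_id = model_id, fnat = fn, ligand_rmsd = lr,
             interface_rmsd = ir,
             quality = capri_class(fn, lr, ir),
             stringsAsFactors = FALSE)
}
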