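# Structure-based cross-link plausibility: Euclidean and
# solvent-accessible surface (SAS) distances between reactive sites,
# the 35 A BS3 reach constraint, and handling of unresolved termini.

# fixed element table; hydrogens ignored (crystal structures rarely
# carry them)
.VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
.VDW_DEFAULT <- 1.7

.element_of <- function(atom_name) {
  el <- substring(gsub("[0-9 ]", "", atom_name), 1, 1)
  el[!el %in% names(.VDW)] <- ""
  el
}

#' Construct a structure model
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `b`.
#' @param seqres Optional named list (by chain) of one-letter sequences
#'   declared for each chain; residues declared but without atoms are
#'   marked unresolved.
#' @return An object of class `structure_model` with `atoms`,
#'   `residues` (per-residue `resolved` flag) and `seqres`.
#' @export
structure_model <- function(atoms, seqres = NULL) {
  stopifnot(all(c("chain", "resno", "resname", "atom", "element",
                  "x", "y", "z", "b") %in% names(atoms)))
  if (nrow(atoms) && any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  res <- unique(atoms[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  res$resolved <- TRUE
  # flag residues declared in seqres (positions 1..n per chain, author
  # numbering assumed to match) or skipped in the numbering as unresolved
  extra <- list()
  for (ch in unique(res$chain)) {
    have <- res$resno[res$chain == ch]
    expect <- if (!is.null(seqres) && !is.null(seqres[[ch]]))
      seq_len(nchar(seqres[[ch]]))
    else if (length(have)) seq(min(have), max(have))
    else integer(0)
    miss <- setdiff(expect, have)
    if (length(miss)) {
      nm <- if (!is.null(seqres) && !is.null(seqres[[ch]])) {
        vapply(miss, function(i)
          .aa_three(substring(seqres[[ch]], i, i)), character(1))
      } else rep("UNK", length(miss))
      extra[[length(extra) + 1L]] <- data.frame(
        chain = ch, resno = miss, resname = nm, resolved = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) res <- rbind(res, do.call(rbind, extra))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(atoms = atoms, residues = res, seqres = seqres),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d chains, %d residues (%d resolved), %d atoms\n",
              length(unique(x$residues$chain)), nrow(x$residues),
              sum(x$residues$resolved), nrow(x$atoms)))
  invisible(x)
}

.AA_132 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa_three <- function(one) {
  r <- .AA_132[one]
  ifelse(is.na(r), "UNK", r)
}
.aa_one <- function(three) {
  r <- names(.AA_132)[match(three, .AA_132)]
  ifelse(is.na(r), "X", r)
}

#' Read a structure model from PDB or mmCIF
#'
#' Residues declared in SEQRES (or the mmCIF entity sequence) without
#' ATOM records, and residues skipped in the author numbering, are
#' flagged unresolved - they carry no coordinates and yield
#' "unconstrained" distance results rather than errors.
#'
#' @param file PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @return A [structure_model()].
#' @export
read_structure <- function(file) {
  if (!file.exists(file)) stop("no such structure file: ", file)
  if (file.size(file) == 0L) stop("empty structure file: ", file)
  ext <- tolower(tools::file_ext(file))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(file) else bio3d::read.pdb(file),
    error = function(e) stop("cannot parse structure file ", file, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$elety %in% c("H")) ,, drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", file)
  el <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
    trimws(at$elesy) else .element_of(at$elety)
  atoms <- data.frame(
    chain = as.character(at$chain), resno = at$resno,
    resname = at$resid, atom = at$elety, element = el,
    x = at$x, y = at$y, z = at$z,
    b = if (is.null(at$b)) 0 else at$b,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres)) {
    chains <- names(pdb$seqres)
    seqres <- lapply(split(pdb$seqres, chains), function(s)
      paste(.aa_one(unname(s)), collapse = ""))
  }
  structure_model(atoms, seqres)
}

#' Write a structure model as a PDB file
#'
#' Emits SEQRES records (so unresolved residues survive a round trip)
#' followed by ATOM records for resolved residues only. Used chiefly by
#' the synthetic-data generator.
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @export
write_structure_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  res <- model$residues
  for (ch in unique(res$chain)) {
    rr <- res[res$chain == ch, , drop = FALSE]
    rn <- rr$resname
    nres <- nrow(rr)
    ser <- 0L
    for (i in seq(1L, nres, by = 13L)) {
      ser <- ser + 1L
      grp <- rn[i:min(i + 12L, nres)]
      writeLines(sprintf("SEQRES %3d %s %4d  %s", ser, ch, nres,
                         paste(sprintf("%-3s", grp), collapse = " ")), con)
    }
  }
  at <- model$atoms
  eleno <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      eleno <- eleno + 1L
      nm <- sub$atom[r]
      nm4 <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        eleno, nm4, sub$resname[r], ch, sub$resno[r],
        sub$x[r], sub$y[r], sub$z[r], 1.0, sub$b[r], sub$element[r]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Locate the reactive atom of a cross-link site
#'
#' Lysine reacts through NZ, the protein N-terminus through the
#' backbone N of the chain's first residue, serine/threonine/tyrosine
#' through OG/OG1/OH. When the named side-chain atom is missing but the
#' residue is resolved, CB (then CA) is used with a recorded 3 A slack.
#' An unresolved residue yields an "unconstrained" marker, never an
#' error: unresolved flexible termini are expected and must not be
#' scored as contradictions.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @param site Residue number, or 0 for the protein N-terminus.
#' @return A list with `status` (`"ok"` or `"unconstrained"`), and for
#'   resolved sites `chain`, `resno`, `atom`, `xyz`, `slack` (A).
#' @export
reactive_atom <- function(model, chain, site) {
  res <- model$residues
  if (site == 0L) {
    rr <- res[res$chain == chain, , drop = FALSE]
    if (!nrow(rr)) stop("unknown chain: ", chain)
    resno <- min(rr$resno)
    target <- "N"
  } else {
    resno <- site
    rr <- res[res$chain == chain & res$resno == resno, , drop = FALSE]
    if (!nrow(rr)) stop("chain ", chain, " has no residue ", site)
    target <- switch(rr$resname[1],
                     LYS = "NZ", SER = "OG", THR = "OG1", TYR = "OH",
                     "CA")
  }
  rrow <- res[res$chain == chain & res$resno == resno, , drop = FALSE]
  if (!rrow$resolved[1])
    return(list(status = "unconstrained", chain = chain, resno = resno))
  at <- model$atoms
  here <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  for (cand in unique(c(target, "CB", "CA"))) {
    hit <- here[here$atom == cand, , drop = FALSE]
    if (nrow(hit)) {
      return(list(status = "ok", chain = chain, resno = resno,
                  atom = cand,
                  xyz = c(hit$x[1], hit$y[1], hit$z[1]),
                  slack = if (cand == target) 0 else 3))
    }
  }
  list(status = "unconstrained", chain = chain, resno = resno)
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric xyz vectors (A).
#' @return Distance in A.
#' @export
euclidean_distance <- function(a, b) {
  sqrt(sum((a - b)^2))
}

#' Solvent-accessible surface distance between two reactive sites
#'
#' Shortest path between the two reactive atoms through
#' solvent-accessible space: a 3-D occupancy grid is built over the
#' model's bounding box (enlarged by `margin` on every side; origin at
#' the enlarged minimum corner); a cell is blocked when its center lies
#' within (van der Waals radius + `probe_radius`) of any heavy atom,
#' except atoms of the two query residues' side chains; the path is a
#' 26-connected uniform-cost search with step costs
#' \{1, sqrt(2), sqrt(3)\} x spacing. Endpoints snap to the nearest
#' free cell (within 2 x spacing, else "buried") and the snap offsets
#' are added. Paths longer than `max_dist` are reported unreachable.
#'
#' @param model A [structure_model()].
#' @param site_a,site_b Lists `(chain, site)` with `site` a residue
#'   number or 0 for the N-terminus, or results of [reactive_atom()].
#' @param grid_spacing Grid spacing, A (default 1.0).
#' @param probe_radius Solvent probe radius, A (default 1.4).
#' @param max_dist Longest path searched, A (default 70 = twice the
#'   35 A constraint).
#' @param margin Grid margin around the bounding box, A (default
#'   `max_dist / 2` so a path can circle the structure).
#' @return A list with `distance` (A, `NA` when not reachable),
#'   `status` (`"ok"`, `"unreachable"`, `"buried"` or
#'   `"unconstrained"`) and `slack` (A of reactive-atom fallback slack).
#' @export
sas_distance <- function(model, site_a, site_b, grid_spacing = 1.0,
                         probe_radius = 1.4, max_dist = 70,
                         margin = max_dist / 2) {
  ra <- if (!is.null(site_a$status)) site_a
        else reactive_atom(model, site_a$chain, site_a$site)
  rb <- if (!is.null(site_b$status)) site_b
        else reactive_atom(model, site_b$chain, site_b$site)
  if (ra$status != "ok" || rb$status != "ok")
    return(list(distance = NA_real_, status = "unconstrained", slack = 0))
  at <- model$atoms
  # the two query residues do not block their own reactive atoms (the
  # N-terminal site's reactive atom is a backbone N, so the whole
  # residue is excluded, not only the side chain)
  query_res <- (at$chain == ra$chain & at$resno == ra$resno) |
               (at$chain == rb$chain & at$resno == rb$resno)
  obst <- at[!query_res & at$element != "H", , drop = FALSE]
  radii <- unname(ifelse(obst$element %in% names(.VDW),
                         .VDW[obst$element], .VDW_DEFAULT))
  res <- .sas_grid_path(as.matrix(obst[, c("x", "y", "z")]), radii,
                        ra$xyz, rb$xyz, grid_spacing, probe_radius,
                        margin, max_dist, 2 * grid_spacing)
  list(distance = res$distance, status = res$status,
       slack = ra$slack + rb$slack)
}

#' Filter cross-links against a structure
#'
#' For each link, the Euclidean and SAS distances between the reactive
#' atoms are computed and compared to the cutoff: `pass` iff
#' `sas <= cutoff + slack` (slack accrues from reactive-atom
#' fallbacks), `fail` otherwise, and `unconstrained` when either site
#' is unresolved - unresolved flexible termini are never counted as
#' contradictions.
#'
#' @param links Data frame with columns `chain_a`, `pos_a`, `chain_b`,
#'   `pos_b` (residue numbers, 0 = N-terminus; `pos_b` may be `NA` for
#'   dead-end links, which are `unconstrained`).
#' @param model A [structure_model()].
#' @param cutoff Maximum plausible SAS distance, A (default 35: 11.4 A
#'   spacer + two lysine side chains + conformational allowance).
#' @param grid_spacing,probe_radius,max_dist See [sas_distance()].
#' @return `links` with `euclidean`, `sas`, `slack` and `within_cutoff`
#'   columns appended.
#' @export
filter_crosslinks <- function(links, model, cutoff = 35,
                              grid_spacing = 1.0, probe_radius = 1.4,
                              max_dist = 2 * cutoff) {
  n <- nrow(links)
  eu <- sas <- slack <- rep(NA_real_, n)
  verdict <- rep("unconstrained", n)
  chains <- unique(model$residues$chain)
  for (r in seq_len(n)) {
    if (!(links$chain_a[r] %in% chains) ||
        (!is.na(links$pos_b[r]) && !(links$chain_b[r] %in% chains)))
      stop("link ", r, " references a chain absent from the model")
    if (is.na(links$pos_b[r])) next  # dead-end: single site, no constraint
    ra <- reactive_atom(model, links$chain_a[r], links$pos_a[r])
    rb <- reactive_atom(model, links$chain_b[r], links$pos_b[r])
    if (ra$status != "ok" || rb$status != "ok") next
    eu[r] <- euclidean_distance(ra$xyz, rb$xyz)
    sd <- sas_distance(model, ra, rb, grid_spacing, probe_radius, max_dist)
    sas[r] <- sd$distance
    slack[r] <- sd$slack
    verdict[r] <- if (!is.na(sd$distance) &&
                        sd$distance <= cutoff + sd$slack) "pass" else "fail"
  }
  links$euclidean <- eu
  links$sas <- sas
  links$slack <- slack
  links$within_cutoff <- verdict
  links
}

#' Cross-linking hotspot report
#'
#' Counts how many links each reactive site participates in, flags
#' N-terminal and unresolved sites, and reports the B-factor of the
#' nearest resolved residue as a flexibility proxy. Sites are sorted by
#' link count, descending.
#'
#' @param links Link table with `chain_a`, `pos_a`, `chain_b`, `pos_b`.
#' @param model A [structure_model()].
#' @return Data frame: `chain`, `pos`, `n_links`, `is_nterm`,
#'   `resolved`, `b_factor`.
#' @export
hotspot_report <- function(links, model) {
  sites <- rbind(
    data.frame(chain = links$chain_a, pos = links$pos_a,
               stringsAsFactors = FALSE),
    data.frame(chain = links$chain_b[!is.na(links$pos_b)],
               pos = links$pos_b[!is.na(links$pos_b)],
               stringsAsFactors = FALSE)
  )
  if (!nrow(sites))
    return(data.frame(chain = character(0), pos = integer(0),
                      n_links = integer(0), is_nterm = logical(0),
                      resolved = logical(0), b_factor = numeric(0),
                      stringsAsFactors = FALSE))
  key <- paste(sites$chain, sites$pos)
  tab <- table(key)
  uniq <- sites[!duplicated(key), , drop = FALSE]
  uniq$n_links <- as.integer(tab[paste(uniq$chain, uniq$pos)])
  uniq$is_nterm <- uniq$pos == 0L
  res <- model$residues
  uniq$resolved <- vapply(seq_len(nrow(uniq)), function(i) {
    rn <- if (uniq$pos[i] == 0L)
      min(res$resno[res$chain == uniq$chain[i]]) else uniq$pos[i]
    any(res$chain == uniq$chain[i] & res$resno == rn & res$resolved)
  }, logical(1))
  uniq$b_factor <- vapply(seq_len(nrow(uniq)), function(i) {
    rn <- if (uniq$pos[i] == 0L)
      min(res$resno[res$chain == uniq$chain[i]]) else uniq$pos[i]
    rr <- res[res$chain == uniq$chain[i] & res$resolved, , drop = FALSE]
    if (!nrow(rr)) return(NA_real_)
    nearest <- rr$resno[which.min(abs(rr$resno - rn))]
    at <- model$atoms
    mean(at$b[at$chain == uniq$chain[i] & at$resno == nearest])
  }, numeric(1))
  uniq <- uniq[order(-uniq$n_links, uniq$chain, uniq$pos), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}
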