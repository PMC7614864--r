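# Morphology: SWC input, synthetic reduced morphologies, d_lambda
# compartmentalization and path distances.

#' Read a neuronal morphology from an SWC file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments) into a section tree. Type codes 1/3/4 map to soma, basal and
#' apical labels; contiguous unbranched sample chains of one type become
#' sections.
#'
#' @param path path to an SWC file.
#' @return A `section_tree` object: list with `sections` (data frame: `id`,
#'   `parent`, `type`) and per-section 3D sample points with diameters (um).
#' @export
load_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (!length(lines)) stop("SWC file has no sample rows")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC row at line ", lineno[bad[1]],
         ": expected 7 columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("malformed SWC row at line ", lineno[bad], ": non-numeric field")
  }
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  xyz <- m[, 3:5, drop = FALSE]; radius <- m[, 6]
  par <- as.integer(m[, 7])
  if (any(radius <= 0)) stop("SWC sample with non-positive radius")
  roots <- which(par == -1L)
  if (length(roots) == 0L) stop("SWC structural error: no root sample")
  if (length(roots) > 1L) stop("SWC structural error: multiple roots")
  idx <- match(par, id)
  miss <- par != -1L & is.na(idx)
  if (any(miss))
    stop("SWC structural error: sample ", id[which(miss)[1]],
         " references missing parent ", par[which(miss)[1]])
  if (type[roots] != 1L)
    stop("SWC structural error: root sample is not soma (type 1)")

  n <- length(id)
  nchild <- tabulate(idx[!is.na(idx)], nbins = n)
  # a sample starts a new section if it is the root, its type differs from
  # its parent's, or its parent is a branch point (or the root soma)
  sec_of <- integer(n)
  sec_parent <- integer(0)  # parent section per section (0 = none)
  sec_type <- integer(0)
  order_ix <- order(id)     # process in id order; SWC requires parent-first
  nsec <- 0L
  for (i in order_ix) {
    p <- idx[i]
    # all contiguous soma samples belong to one root section; other types
    # split at type changes and branch points
    new_sec <- is.na(p) || type[p] != type[i] ||
      (nchild[p] > 1L && type[i] != 1L)
    if (new_sec) {
      nsec <- nsec + 1L
      sec_of[i] <- nsec
      sec_parent[nsec] <- if (is.na(p)) 0L else sec_of[p]
      sec_type[nsec] <- type[i]
    } else {
      sec_of[i] <- sec_of[p]
    }
  }
  type_lab <- c("soma", "axon", "basal", "apical")
  lab <- function(tc) {
    if (tc >= 1 && tc <= 4) type_lab[tc] else "basal"
  }
  secs <- vector("list", nsec)
  sec_samples <- vector("list", nsec)  # sample indices per section, in order
  for (s in seq_len(nsec)) sec_samples[[s]] <- order_ix[sec_of[order_ix] == s]
  attach <- integer(nsec)              # attachment row in the parent points
  for (s in seq_len(nsec)) {
    ix <- sec_samples[[s]]
    pts <- cbind(xyz[ix, , drop = FALSE], diam = 2 * radius[ix])
    # prepend the attachment point so the section has geometric extent
    p1 <- idx[ix[1]]
    if (!is.na(p1)) {
      pts <- rbind(cbind(xyz[p1, , drop = FALSE], diam = 2 * radius[ix[1]]),
                   pts)
      ps <- sec_of[p1]
      row <- match(p1, sec_samples[[ps]])
      attach[s] <- row + (if (sec_parent[ps] > 0L) 1L else 0L)
    }
    colnames(pts) <- c("x", "y", "z", "diam")
    secs[[s]] <- list(type = lab(sec_type[s]), points = pts)
  }
  tree <- structure(list(
    sections = data.frame(id = seq_len(nsec), parent = sec_parent,
                          type = vapply(secs, `[[`, "", "type")),
    geometry = lapply(secs, `[[`, "points"),
    attach = attach), class = "section_tree")
  validate_tree(tree)
  tree
}

#' Write a section tree to SWC text
#'
#' Inverse of [load_swc()] for round-trip checks; emits one sample per
#' section point (attachment points are not duplicated).
#'
#' @param tree a `section_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  type_code <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)
  rows <- list(); nid <- 0L
  ids <- vector("list", nrow(tree$sections))  # sample id per point row
  attach <- tree$attach
  if (is.null(attach))                        # default: parent section end
    attach <- vapply(tree$sections$parent, function(p)
      if (p > 0L) nrow(tree$geometry[[p]]) else 0L, 0L)
  for (s in seq_len(nrow(tree$sections))) {
    pts <- tree$geometry[[s]]
    par_sec <- tree$sections$parent[s]
    start <- if (par_sec > 0L) 2L else 1L  # skip duplicated attachment point
    prev <- if (par_sec > 0L) ids[[par_sec]][attach[s]] else -1L
    ids[[s]] <- integer(nrow(pts))
    if (par_sec > 0L) ids[[s]][1] <- prev
    for (k in start:nrow(pts)) {
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <-
        sprintf("%d %d %.6f %.6f %.6f %.6f %d", nid,
                type_code[[tree$sections$type[s]]],
                pts[k, 1], pts[k, 2], pts[k, 3], pts[k, 4] / 2, prev)
      ids[[s]][k] <- nid
      prev <- nid
    }
  }
  writeLines(c("# ca3pop section tree", unlist(rows)), path)
  invisible(path)
}

validate_tree <- function(tree) {
  secs <- tree$sections
  if (sum(secs$parent == 0L) != 1L)
    stop("section tree must have a single root section")
  if (secs$type[secs$parent == 0L] != "soma")
    stop("root section must be soma")
  for (s in seq_len(nrow(secs))) {
    if (secs$parent[s] >= s && secs$parent[s] != 0L)
      stop("sections must be ordered parent-first")
    pts <- tree$geometry[[s]]
    if (any(pts[, "diam"] <= 0)) stop("all diameters must be positive")
    if (s > 1 && section_length(tree, s) <= 0)
      stop("section ", s, " has zero length")
  }
  invisible(tree)
}

section_length <- function(tree, s) {
  pts <- tree$geometry[[s]]
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts[, 1:3, drop = FALSE])^2)))
}

#' Build a reduced synthetic CA3-like morphology
#'
#' Constructs a ball-and-stick style section tree: a cylindrical soma, an
#' apical trunk (split into sections at the 150 um and 300 um recording
#' sites so those locations fall on compartment boundaries), optional
#' oblique branches in the stratum radiatum, and basal equivalent cylinders.
#' The default geometry gives a total membrane area in the range of a CA3b
#' pyramidal cell (~5e-4 cm^2) so that input resistance with R_m = 60
#' kOhm cm^2 lands in the physiological window.
#'
#' @param soma_length,soma_diam soma cylinder dimensions (um).
#' @param trunk_length,trunk_diam apical trunk dimensions (um).
#' @param n_oblique number of oblique branches (0 for a plain stick).
#' @param oblique_length,oblique_diam oblique dimensions (um).
#' @param oblique_attach path distances (um) of oblique origins on the trunk;
#'   recycled to `n_oblique`.
#' @param n_basal,basal_length,basal_diam basal equivalent cylinders.
#' @param require_bap_sites if `TRUE` (default), error when the apical trunk
#'   does not reach 300 um (the distal backpropagation recording site).
#' @return A `section_tree`.
#' @export
build_synthetic_morphology <- function(
    soma_length = 20, soma_diam = 20,
    trunk_length = 500, trunk_diam = c(6, 3.5, 2),
    n_oblique = 2, oblique_length = 150, oblique_diam = 3,
    oblique_attach = c(150, 300),
    n_basal = 2, basal_length = 420, basal_diam = 16,
    require_bap_sites = TRUE) {
  dims <- c(soma_length, soma_diam, trunk_length, trunk_diam,
            oblique_length, oblique_diam, basal_length, basal_diam)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (require_bap_sites && trunk_length < 300)
    stop("apical trunk must span at least 300 um for the backpropagation ",
         "recording sites; got ", trunk_length)

  secs <- list(); geom <- list()
  add <- function(type, parent, pts) {
    secs[[length(secs) + 1L]] <<- list(type = type, parent = parent)
    geom[[length(geom) + 1L]] <<- pts
    length(secs)
  }
  pt <- function(x, y, d) cbind(x = x, y = y, z = 0, diam = d)
  soma <- add("soma", 0L, pt(c(-soma_length / 2, soma_length / 2), c(0, 0),
                             soma_diam))
  # apical trunk along +y, broken at the recording sites; the diameter may
  # taper section by section (recycled over the trunk sections)
  brk <- sort(unique(c(150, 300, trunk_length)))
  brk <- brk[brk <= trunk_length]
  tdiam <- rep_len(trunk_diam, length(brk))
  prev <- soma; y0 <- 0
  trunk_ids <- integer(0)
  for (bi in seq_along(brk)) {
    b <- brk[bi]
    sid <- add("apical", prev, pt(c(0, 0), c(y0, b), tdiam[bi]))
    trunk_ids <- c(trunk_ids, sid); prev <- sid; y0 <- b
  }
  if (n_oblique > 0) {
    att <- rep_len(oblique_attach, n_oblique)
    for (k in seq_len(n_oblique)) {
      a <- min(att[k], trunk_length)
      host <- trunk_ids[which(brk >= a)[1]]
      sid <- add("apical", host,
                 pt(c(0, oblique_length), c(a, a), oblique_diam))
      # shift the oblique start to its attachment height
      geom[[sid]][, "x"] <- c(0, oblique_length)
      geom[[sid]][, "y"] <- a
    }
  }
  for (k in seq_len(n_basal)) {
    ang <- pi + (k - (n_basal + 1) / 2) * 0.5
    add("basal", soma,
        pt(c(0, basal_length * cos(ang)), c(0, basal_length * sin(ang)),
           basal_diam))
  }
  tree <- structure(list(
    sections = data.frame(id = seq_along(secs),
                          parent = vapply(secs, `[[`, 0L, "parent"),
                          type = vapply(secs, `[[`, "", "type")),
    geometry = geom), class = "section_tree")
  validate_tree(tree)
  tree
}

#' Total membrane area of a section tree (cm^2)
#'
#' Lateral cylinder/frustum area summed over all sections; the soma is
#' treated as an equivalent cylinder.
#'
#' @param tree a `section_tree`.
#' @return area in cm^2.
#' @export
tree_area <- function(tree) {
  a_um2 <- 0
  for (s in seq_len(nrow(tree$sections))) {
    pts <- tree$geometry[[s]]
    if (nrow(pts) < 2) next
    seg <- sqrt(rowSums(diff(pts[, 1:3, drop = FALSE])^2))
    dmean <- (pts[-1, "diam"] + pts[-nrow(pts), "diam"]) / 2
    a_um2 <- a_um2 + sum(pi * dmean * seg)
  }
  a_um2 * 1e-8
}

#' AC length constant of a cylinder at frequency f
#'
#' `lambda_f = 0.5e5 * sqrt(diam / (pi f R_a C_m))` um, the alternating-
#' current space constant used by the d_lambda discretization rule.
#'
#' @param diam_um cylinder diameter (um).
#' @param f frequency (Hz).
#' @param ra axial resistivity (Ohm cm).
#' @param cm specific capacitance (uF/cm^2).
#' @return length constant in um.
#' @export
lambda_f <- function(diam_um, f, ra, cm) {
  if (f <= 0) stop("frequency must be positive")
  1e5 * 0.5 * sqrt(diam_um / (pi * f * ra * cm))
}

#' Discretize a section tree into iso-potential compartments
#'
#' Applies the d_lambda rule: each section is split into the smallest odd
#' number of compartments that keeps every compartment shorter than
#' `d_lambda` times the AC length constant at frequency `f`.
#'
#' @param tree a `section_tree`.
#' @param d_lambda fraction of the AC length constant (default 0.1).
#' @param f reference frequency in Hz (default 100).
#' @param rm specific membrane resistivity (kOhm cm^2).
#' @param ra axial resistivity (Ohm cm).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param e_pas leak reversal potential (mV).
#' @param sr_window stratum-radiatum path-distance window on the apical
#'   tree (um), used for region labels and synapse placement.
#' @return A `compartmental_model`: compartment table (section, position,
#'   length, diameter, membrane area, path distance from the soma centre,
#'   region), parent links with axial coupling conductances (uS), and the
#'   passive constants.
#' @export
discretize <- function(tree, d_lambda = 0.1, f = 100,
                       rm = 60, ra = 200, cm = 0.75, e_pas = -63.5,
                       sr_window = c(50, 300)) {
  stopifnot(d_lambda > 0, d_lambda <= 1)
  if (f <= 0) stop("frequency must be positive")
  if (rm <= 0 || ra <= 0 || cm <= 0) stop("passive constants must be positive")
  nsec <- nrow(tree$sections)
  comp <- list(); parent_comp <- integer(0)
  sec_first <- sec_last <- integer(nsec)
  sec_end_dist <- numeric(nsec)
  nid <- 0L
  for (s in seq_len(nsec)) {
    pts <- tree$geometry[[s]]
    L <- section_length(tree, s)
    dmean <- mean(pts[, "diam"])
    type <- tree$sections$type[s]
    psec <- tree$sections$parent[s]
    x0 <- if (psec > 0L) sec_end_dist[psec] else 0
    if (type == "soma") {
      nseg <- 1L
      x0 <- 0
    } else {
      lam <- lambda_f(dmean, f, ra, cm)
      nseg <- ceiling(L / (d_lambda * lam))
      if (nseg %% 2 == 0) nseg <- nseg + 1L
    }
    len <- L / nseg
    for (k in seq_len(nseg)) {
      nid <- nid + 1L
      if (k == 1L) sec_first[s] <- nid
      comp[[nid]] <- data.frame(
        section = s, pos = (k - 0.5) / nseg, length_um = len,
        diam_um = dmean, area_cm2 = pi * dmean * len * 1e-8,
        path_um = if (type == "soma") 0 else x0 + (k - 0.5) * len,
        region = type, stringsAsFactors = FALSE)
      parent_comp[nid] <- if (k > 1L) nid - 1L
        else if (psec > 0L) sec_last[psec] else 0L
    }
    sec_last[s] <- nid
    sec_end_dist[s] <- if (type == "soma") 0 else x0 + L
  }
  comp <- do.call(rbind, comp)
  comp$region <- ifelse(
    comp$region == "apical" & comp$path_um >= sr_window[1] &
      comp$path_um <= sr_window[2],
    "apical_sr", comp$region)
  n <- nrow(comp)
  # axial coupling: series sum of the two half-compartment resistances
  g_ax <- numeric(n)
  for (i in seq_len(n)) {
    p <- parent_comp[i]
    if (p == 0L) next
    rhalf <- function(j) {
      r_cm <- comp$diam_um[j] / 2 * 1e-4
      ra * (comp$length_um[j] / 2 * 1e-4) / (pi * r_cm^2)  # Ohm
    }
    g_ax[i] <- 1e6 / (rhalf(i) + rhalf(p))  # uS
  }
  structure(list(
    comp = comp, parent = parent_comp, g_ax_uS = g_ax,
    cm_nF = cm * comp$area_cm2 * 1e3,
    g_pas = rep(1 / rm, n),  # mS/cm^2 (rm in kOhm cm^2)
    e_pas = e_pas, rm = rm, ra = ra, cm = cm,
    d_lambda = d_lambda, f_lambda = f, sr_window = sr_window,
    tree = tree), class = "compartmental_model")
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat("compartmental_model:", nrow(x$comp), "compartments,",
      nrow(x$tree$sections), "sections,",
      sprintf("area %.3g cm^2", sum(x$comp$area_cm2)), "\n")
  invisible(x)
}

#' Path distance of a compartment from the soma centre (um)
#'
#' @param model a `compartmental_model`.
#' @param comp compartment index.
#' @return arc-length distance in um.
#' @export
path_distance <- function(model, comp) {
  if (any(comp < 1) || any(comp > nrow(model$comp)))
    stop("unknown compartment: ", comp[1])
  model$comp$path_um[comp]
}

#' Resolve a named recording site to a compartment index
#'
#' `"soma"` resolves to the root compartment; `"apical150"`/`"apical300"`
#' to the apical compartment nearest 150/300 um path distance; a numeric
#' string `"apicalX"` generalizes.
#'
#' @param model a `compartmental_model`.
#' @param site site name or compartment index.
#' @return compartment index.
#' @export
resolve_site <- function(model, site) {
  if (is.numeric(site)) return(as.integer(site))
  if (site == "soma") return(which(model$comp$region == "soma")[1])
  m <- regmatches(site, regexec("^apical(\\d+)$", site))[[1]]
  if (length(m) == 2) {
    x <- as.numeric(m[2])
    ap <- which(startsWith(model$comp$region, "apical"))
    if (!length(ap)) stop("model has no apical compartments")
    return(ap[which.min(abs(model$comp$path_um[ap] - x))])
  }
  stop("unknown recording site: ", site)
}
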