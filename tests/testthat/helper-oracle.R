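# Independent brute-force single-cut oracle for analog-series extraction.
#
# Deliberately coded on a different path from the package: molecular graphs
# come from ChemmineR SDF atom/bond blocks, acyclic-bond detection is a
# plain DFS disconnection test, fragments are written as hand-built V2000
# molfiles, and canonical SMILES are produced by the obabel command-line
# tool. Only the final canonical-string labels share the underlying Open
# Babel library with the implementation.

oracle_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a = integer(), b = integer(), order = integer())
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds)
}

# atoms reachable from `start` when bond `skip` is removed
oracle_component <- function(g, start, skip) {
  n <- length(g$elements)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    if (i == skip) next
    a <- g$bonds$a[i]; b <- g$bonds$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]])
  }
  which(seen)
}

# V2000 molfile for the atom subset `atoms` of graph g; `attach_at` (original
# index) optionally gets a dummy neighbor representing the cut.
oracle_molfile <- function(g, atoms, attach_at = NULL, title = "frag") {
  local_idx <- seq_along(atoms)
  names(local_idx) <- atoms
  els <- g$elements[atoms]
  keep <- g$bonds$a %in% atoms & g$bonds$b %in% atoms
  bnd <- g$bonds[keep, , drop = FALSE]
  a_loc <- local_idx[as.character(bnd$a)]
  b_loc <- local_idx[as.character(bnd$b)]
  ords <- bnd$order
  if (!is.null(attach_at)) {
    els <- c(els, "*")
    a_loc <- c(a_loc, local_idx[as.character(attach_at)])
    b_loc <- c(b_loc, length(els))
    ords <- c(ords, 1L)
  }
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, els)
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0", a_loc, b_loc, ords)
  paste(c(title, " oracle", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(els), length(ords)),
          atom_lines, bond_lines, "M  END", "$$$$"), collapse = "\n")
}

# Canonicalize many molfile blocks in one obabel call; returns SMILES named
# by molfile title. Stereo/isotope marks are dropped (-xi).
oracle_obabel_canonical <- function(molfiles) {
  if (length(molfiles) == 0L) return(character(0))
  inp <- tempfile(fileext = ".sdf")
  writeLines(paste(molfiles, collapse = "\n"), inp, useBytes = TRUE)
  out <- suppressWarnings(
    system2("obabel", c("-isdf", inp, "-ocan", "-xi"),
            stdout = TRUE, stderr = FALSE))
  unlink(inp)
  out <- out[nzchar(trimws(out))]
  parts <- strsplit(out, "\t", fixed = TRUE)
  smi <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  names(smi) <- vapply(parts, function(p)
    trimws(if (length(p) >= 2L) p[[2]] else ""), character(1))
  smi
}

# Exhaustive single-cut enumeration over a compound table under the fixed
# policy: all acyclic single bonds between heavy atoms, substituent strictly
# smaller than the core, substituent <= max_sub heavy atoms, hydrogen analogs
# admitted when allow_h is TRUE. Returns core -> sorted member-cid set for
# cores with >= 2 distinct members.
oracle_build_series <- function(compounds, max_sub = 13L, allow_h = TRUE) {
  molfiles <- list()
  cuts <- list()          # per cut: cid, key_core, key_parent, size_core, size_sub, key_sub
  for (i in seq_len(nrow(compounds))) {
    cid <- compounds$cid[i]
    g <- oracle_graph(compounds$smiles[i])
    heavy <- which(g$elements != "H")
    for (j in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[j] != 1L) next
      a <- g$bonds$a[j]; b <- g$bonds$b[j]
      if (!(a %in% heavy && b %in% heavy)) next
      comp_a <- oracle_component(g, a, skip = j)
      if (b %in% comp_a) next   # ring bond: removal does not disconnect
      comp_b <- setdiff(seq_along(g$elements), comp_a)
      sz_a <- sum(g$elements[comp_a] != "H")
      sz_b <- sum(g$elements[comp_b] != "H")
      if (sz_a == sz_b) next                       # no strict core
      if (sz_a > sz_b) {
        core_atoms <- comp_a; core_at <- a; sub_atoms <- comp_b; sub_at <- b
        sz_sub <- sz_b
      } else {
        core_atoms <- comp_b; core_at <- b; sub_atoms <- comp_a; sub_at <- a
        sz_sub <- sz_a
      }
      if (sz_sub > max_sub) next
      kc <- sprintf("c%d", length(molfiles) + 1L)
      molfiles[[kc]] <- oracle_molfile(g, core_atoms, core_at, title = kc)
      kp <- sprintf("p%d", length(molfiles) + 1L)
      molfiles[[kp]] <- oracle_molfile(g, core_atoms, NULL, title = kp)
      ks <- sprintf("s%d", length(molfiles) + 1L)
      molfiles[[ks]] <- oracle_molfile(g, sub_atoms, sub_at, title = ks)
      cuts[[length(cuts) + 1L]] <- list(cid = cid, core = kc, parent = kp,
                                        sub = ks)
    }
  }
  smi <- oracle_obabel_canonical(unlist(molfiles))
  memberships <- list()   # core smiles -> cids
  parents <- list()       # core smiles -> parent smiles
  for (ct in cuts) {
    core <- smi[[ct$core]]
    memberships[[core]] <- c(memberships[[core]], ct$cid)
    parents[[core]] <- smi[[ct$parent]]
  }
  if (allow_h) {
    for (core in names(parents)) {
      hit <- compounds$cid[compounds$smiles == parents[[core]]]
      if (length(hit)) memberships[[core]] <- c(memberships[[core]], hit)
    }
  }
  memberships <- lapply(memberships, function(x) sort(unique(x)))
  memberships[vapply(memberships, length, integer(1)) >= 2L]
}
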