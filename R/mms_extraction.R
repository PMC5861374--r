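#' Retrosynthetic bond-cleavage rules
#'
#' The default rule set used for retrosynthetic fragmentation. Each rule is a
#' SMARTS pattern that maps exactly two atoms (environment conditions go into
#' recursive SMARTS); the bond between the two mapped atoms is cleavable. The
#' shipped set covers the classic RECAP-style lability points: amide C-N,
#' ester C-O, sulfonamide S-N, amine C-N and ether C-O, restricted to acyclic
#' bonds and to sp3 carbon partners so that bonds adjacent to olefinic C=C are
#' not cut.
#'
#' @return data.frame with columns `pattern_id`, `smarts`.
#' @export
default_retro_patterns <- function() {
  data.frame(
    pattern_id = c("amide", "ester", "sulfonamide", "amine", "ether"),
    smarts = c(
      "[CX3;$([CX3]=[OX1])]!@[NX3]",
      "[CX3;$([CX3]=[OX1])]!@[OX2;$([OX2][#6])]",
      "[SX4;$([SX4](=[OX1])=[OX1])]!@[NX3]",
      "[NX3;!$([NX3]=*);!$([NX3][CX3]=[OX1]);!$([NX3][SX4])]!@[CX4]",
      "[OX2;$([OX2]([#6])[#6]);!$([OX2][CX3]=[OX1])]!@[CX4]"
    )
  )
}

#' Read retrosynthetic rules from a file
#'
#' One SMARTS per line, optionally followed by whitespace and an identifier;
#' `#` starts a comment. Every pattern must parse and must map exactly two
#' atoms (the cleavable bond).
#'
#' @param path path to the rules file.
#' @return data.frame with columns `pattern_id`, `smarts`.
#' @export
read_retro_patterns <- function(path) {
  if (!file.exists(path)) stop("retro pattern file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no patterns in ", path, call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  smarts <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else paste0("rule", i)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate pattern id in ", path, call. = FALSE)
  pat <- data.frame(pattern_id = ids, smarts = smarts)
  validate_retro_patterns(pat)
  pat
}

validate_retro_patterns <- function(patterns) {
  stopifnot(is.data.frame(patterns),
            all(c("pattern_id", "smarts") %in% names(patterns)))
  for (i in seq_len(nrow(patterns))) {
    sp <- ob_smarts(patterns$smarts[i])   # errors on invalid SMARTS
    n <- ob_smarts_num_atoms(sp)
    ob_smarts_free(sp)
    if (n != 2L) {
      stop("retro pattern '", patterns$pattern_id[i],
           "' must map exactly 2 atoms (maps ", n, ")", call. = FALSE)
    }
  }
  invisible(patterns)
}

#' Fragmentation policy for analog-series extraction
#'
#' Controls which single acyclic bonds between heavy atoms are cut when
#' enumerating fragmentations, and how the resulting fragments are assigned to
#' core and substituent roles.
#'
#' @param bond_rule `"retrosynthetic"` (cut only bonds matching one of the
#'   `retro_patterns`; production default) or `"all_acyclic"` (cut every
#'   single acyclic bond; used for exhaustive/oracle work).
#' @param retro_patterns data.frame (`pattern_id`, `smarts`) of two-atom bond
#'   rules; see [default_retro_patterns()] and [read_retro_patterns()].
#' @param max_substituent_heavy_atoms substituent size cap, in heavy atoms
#'   excluding the attachment point (default 13, the common matched-molecular-
#'   pair convention).
#' @param require_substituent_smaller_than_core when TRUE (default) the
#'   substituent must be strictly smaller than the core; equal-sized fragments
#'   yield no fragmentation. When FALSE both fragments may serve as the
#'   substituent, each emitted as an alternative fragmentation if it passes
#'   the size cap.
#' @param allow_hydrogen_substituent when TRUE (default) the unsubstituted
#'   parent compound (hydrogen at the attachment point) is admitted as a
#'   series member with substituent `"[*][H]"`.
#' @return object of class `fragmentation_policy`.
#' @export
fragmentation_policy <- function(bond_rule = c("retrosynthetic", "all_acyclic"),
                                 retro_patterns = default_retro_patterns(),
                                 max_substituent_heavy_atoms = 13L,
                                 require_substituent_smaller_than_core = TRUE,
                                 allow_hydrogen_substituent = TRUE) {
  bond_rule <- match.arg(bond_rule)
  stopifnot(is.numeric(max_substituent_heavy_atoms),
            max_substituent_heavy_atoms >= 1)
  if (bond_rule == "retrosynthetic") {
    if (is.null(retro_patterns) || nrow(retro_patterns) == 0L) {
      stop("retrosynthetic mode needs a non-empty pattern set", call. = FALSE)
    }
    validate_retro_patterns(retro_patterns)
  }
  structure(list(bond_rule = bond_rule,
                 retro_patterns = retro_patterns,
                 max_substituent_heavy_atoms = as.integer(max_substituent_heavy_atoms),
                 require_substituent_smaller_than_core =
                   isTRUE(require_substituent_smaller_than_core),
                 allow_hydrogen_substituent = isTRUE(allow_hydrogen_substituent)),
            class = "fragmentation_policy")
}

# Substituent token for the hydrogen analog (unsubstituted parent).
H_SUBSTITUENT <- "[*][H]"

is_h_substituent <- function(s) {
  s %in% c("[*][H]", "*[H]", "[H][*]", "[H]*")
}

# Canonicalize a fragment SMILES and count its heavy atoms, excluding the
# attachment dummy (atomic number 0, which Open Babel counts as heavy).
fragment_info <- function(smiles) {
  mol <- ob_parse(smiles)
  if (is.null(mol)) stop("unparsable fragment SMILES: ", smiles, call. = FALSE)
  atnum <- ob_atomic_numbers(mol)
  out <- list(smiles = ob_write_canonical(mol),
              heavy = sum(atnum > 1L),   # H (1) and the dummy (0) excluded
              n_attach = sum(atnum == 0L))
  ob_free(mol)
  out
}

#' Count attachment-point tokens in a SMILES string
#'
#' @param smiles character vector.
#' @return integer vector: number of dummy atoms (`[*]`) in each structure.
#' @export
n_attachment_points <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- ob_parse(s)
    if (is.null(mol)) stop("unparsable SMILES: ", s, call. = FALSE)
    n <- sum(ob_atomic_numbers(mol) == 0L)
    ob_free(mol)
    as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
}

#' Enumerate single-cut fragmentations of a compound
#'
#' Cuts, one at a time, every eligible bond of the compound: single-order,
#' acyclic, between two heavy atoms, and (under the retrosynthetic rule)
#' matching one of the policy's bond patterns. Each cut yields a core and a
#' substituent fragment, both written as canonical aromatic non-stereo SMILES
#' with a single `[*]` attachment token, assigned per the policy's size rules.
#'
#' @param smiles a single SMILES string (canonicalized internally).
#' @param policy a [fragmentation_policy()].
#' @param cid compound id carried into the result (default `NA`).
#' @return data.frame with columns `cid`, `core_smiles`, `substituent_smiles`,
#'   `substituent_heavy_atoms`; zero rows when no bond is eligible.
#' @export
enumerate_cuts <- function(smiles, policy = fragmentation_policy(),
                           cid = NA_character_) {
  stopifnot(length(smiles) == 1L, inherits(policy, "fragmentation_policy"))
  empty <- data.frame(cid = character(), core_smiles = character(),
                      substituent_smiles = character(),
                      substituent_heavy_atoms = integer())
  mol <- ob_parse(smiles)
  if (is.null(mol)) stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  atnum <- ob_atomic_numbers(mol)
  bonds <- ob_bond_table(mol)
  eligible <- bonds[bonds$order == 1L & !bonds$in_ring &
                      atnum[bonds$begin] > 1L & atnum[bonds$end] > 1L, ,
                    drop = FALSE]
  if (nrow(eligible) > 0L && policy$bond_rule == "retrosynthetic") {
    allowed <- character(0)
    for (i in seq_len(nrow(policy$retro_patterns))) {
      sp <- ob_smarts(policy$retro_patterns$smarts[i])
      for (m in ob_smarts_matches(sp, mol)) {
        allowed <- c(allowed, paste(min(m), max(m)))
      }
      ob_smarts_free(sp)
    }
    key <- paste(pmin(eligible$begin, eligible$end),
                 pmax(eligible$begin, eligible$end))
    eligible <- eligible[key %in% allowed, , drop = FALSE]
  }
  ob_free(mol)
  if (nrow(eligible) == 0L) return(empty)

  rows <- vector("list", 2L * nrow(eligible))
  k <- 0L
  for (i in seq_len(nrow(eligible))) {
    # fresh parse: atom and bond indexing of the same input string is stable
    work <- ob_parse(smiles)
    frag <- ob_cut_bond(work, eligible$bond[i])
    ob_free(work)
    parts <- strsplit(frag, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) next   # defensive; acyclic cut always gives 2
    f1 <- fragment_info(parts[1]); f2 <- fragment_info(parts[2])
    emit <- function(core, sub) {
      if (sub$heavy > policy$max_substituent_heavy_atoms) return()
      k <<- k + 1L
      rows[[k]] <<- data.frame(cid = cid, core_smiles = core$smiles,
                               substituent_smiles = sub$smiles,
                               substituent_heavy_atoms = sub$heavy)
    }
    if (policy$require_substituent_smaller_than_core) {
      if (f1$heavy < f2$heavy) emit(f2, f1)
      else if (f2$heavy < f1$heavy) emit(f1, f2)
      # equal sizes: no valid core/substituent assignment
    } else {
      emit(f2, f1)
      emit(f1, f2)
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, rows[seq_len(k)])
}

#' Reattach a substituent to a core
#'
#' Joins a core and a substituent fragment, each carrying exactly one `[*]`
#' attachment token, by a single bond between the attachment neighbors, and
#' returns the canonical aromatic non-stereo SMILES of the reassembled
#' compound. The hydrogen substituent `"[*][H]"` yields the unsubstituted
#' parent (see [core_to_parent()]).
#'
#' @param core_smiles core fragment SMILES with one attachment token.
#' @param substituent_smiles substituent fragment SMILES with one attachment
#'   token.
#' @return canonical SMILES of the reassembled compound.
#' @export
reattach_fragments <- function(core_smiles, substituent_smiles) {
  stopifnot(length(core_smiles) == 1L, length(substituent_smiles) == 1L)
  if (is_h_substituent(substituent_smiles)) return(core_to_parent(core_smiles))
  OB <- ob()
  mol <- ob_parse(paste(core_smiles, substituent_smiles, sep = "."))
  if (is.null(mol)) {
    stop("unparsable fragment pair: '", core_smiles, "' + '",
         substituent_smiles, "'", call. = FALSE)
  }
  atnum <- ob_atomic_numbers(mol)
  dummies <- which(atnum == 0L)
  if (length(dummies) != 2L) {
    ob_free(mol)
    stop("core and substituent must each contain exactly one attachment point",
         call. = FALSE)
  }
  nbrs <- lapply(dummies, function(d) {
    OB$OBMol_GetAtom(mol, ob_single_neighbor(mol, d))
  })
  for (d in sort(dummies, decreasing = TRUE)) {
    OB$OBMol_DeleteAtom(mol, OB$OBMol_GetAtom(mol, d))
  }
  OB$OBMol_AddBond(mol, OB$OBAtom_GetIdx(nbrs[[1]]),
                   OB$OBAtom_GetIdx(nbrs[[2]]), 1L)
  out <- ob_write_canonical(mol)
  ob_free(mol)
  out
}

#' Unsubstituted parent of a core fragment
#'
#' Replaces the attachment point of a core by hydrogen (the dummy atom is
#' removed and the open valence filled implicitly).
#'
#' @param core_smiles character vector of core SMILES, each with exactly one
#'   attachment token.
#' @return character vector of canonical parent SMILES.
#' @export
core_to_parent <- function(core_smiles) {
  OB <- ob()
  vapply(core_smiles, function(s) {
    mol <- ob_parse(s)
    if (is.null(mol)) stop("unparsable core SMILES: ", s, call. = FALSE)
    dummies <- which(ob_atomic_numbers(mol) == 0L)
    if (length(dummies) != 1L) {
      ob_free(mol)
      stop("core must contain exactly one attachment point: ", s, call. = FALSE)
    }
    # the freed valence is filled by an implicit hydrogen
    nbr <- OB$OBMol_GetAtom(mol, ob_single_neighbor(mol, dummies))
    OB$OBMol_DeleteAtom(mol, OB$OBMol_GetAtom(mol, dummies))
    OB$OBAtom_SetImplicitHCount(nbr, OB$OBAtom_GetImplicitHCount(nbr) + 1L)
    out <- ob_write_canonical(mol)
    ob_free(mol)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Build analog series from a compound set
#'
#' Enumerates single-cut fragmentations for every compound under the policy,
#' indexes them by canonical core SMILES, and turns every core shared by at
#' least two distinct compounds into one analog series. When the policy admits
#' hydrogen substituents, a library compound identical to a core's
#' unsubstituted parent joins that series with substituent `"[*][H]"`.
#'
#' Series identifiers are sequential integers assigned after sorting cores
#' lexicographically (C locale), so they are deterministic across runs and
#' input orderings. Members are sorted by compound id within each series. Two
#' compound ids mapping to the identical structure (same core and same
#' substituent) would be duplicate structures; only the lexicographically
#' smallest id is kept, with a warning.
#'
#' @param compounds data.frame with columns `cid` (unique) and `smiles`.
#' @param policy a [fragmentation_policy()].
#' @return object of class `analog_series_set`: list with `series`
#'   (data.frame `as_id`, `core_smiles`, `n_members`) and `members`
#'   (data.frame `as_id`, `cid`, `substituent_smiles`).
#' @export
build_series <- function(compounds, policy = fragmentation_policy()) {
  stopifnot(is.data.frame(compounds),
            all(c("cid", "smiles") %in% names(compounds)))
  cid <- as.character(compounds$cid)
  if (anyDuplicated(cid)) {
    stop("duplicate compound id(s) in input: ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "), call. = FALSE)
  }
  smiles <- canonicalize_smiles(as.character(compounds$smiles))

  frag_list <- vector("list", length(cid))
  for (i in seq_along(cid)) {
    frag_list[[i]] <- enumerate_cuts(smiles[i], policy, cid = cid[i])
  }
  frags <- do.call(rbind, frag_list)
  if (is.null(frags) || nrow(frags) == 0L) return(empty_series_set())
  frags <- frags[!duplicated(frags[c("cid", "core_smiles", "substituent_smiles")]), ,
                 drop = FALSE]

  if (policy$allow_hydrogen_substituent) {
    cores <- unique(frags$core_smiles)
    parents <- core_to_parent(cores)
    hits <- which(parents %in% smiles)
    if (length(hits) > 0L) {
      extra <- do.call(rbind, lapply(hits, function(j) {
        match_cids <- cid[smiles == parents[j]]
        data.frame(cid = match_cids, core_smiles = cores[j],
                   substituent_smiles = H_SUBSTITUENT,
                   substituent_heavy_atoms = 0L)
      }))
      frags <- rbind(frags, extra)
      frags <- frags[!duplicated(frags[c("cid", "core_smiles", "substituent_smiles")]), ,
                     drop = FALSE]
    }
  }

  # duplicate structures: same (core, substituent) under different ids
  frags <- frags[order(frags$cid, method = "radix"), , drop = FALSE]
  struct_key <- paste(frags$core_smiles, frags$substituent_smiles, sep = "\r")
  dup_struct <- duplicated(struct_key)
  if (any(dup_struct)) {
    warning(sum(dup_struct), " duplicate structure membership(s) dropped ",
            "(same core and substituent under different compound ids)",
            call. = FALSE)
    frags <- frags[!dup_struct, , drop = FALSE]
  }

  per_core <- split(frags, frags$core_smiles)
  keep <- vapply(per_core, function(d) length(unique(d$cid)) >= 2L, logical(1))
  per_core <- per_core[keep]
  if (length(per_core) == 0L) return(empty_series_set())

  cores <- sort(names(per_core), method = "radix")
  members <- do.call(rbind, lapply(seq_along(cores), function(i) {
    d <- per_core[[cores[i]]]
    d <- d[order(d$cid, method = "radix"), , drop = FALSE]
    data.frame(as_id = i, cid = d$cid,
               substituent_smiles = d$substituent_smiles)
  }))
  series <- data.frame(as_id = seq_along(cores), core_smiles = cores,
                       n_members = vapply(cores, function(cr)
                         nrow(per_core[[cr]]), integer(1), USE.NAMES = FALSE))
  structure(list(series = series, members = members),
            class = "analog_series_set")
}

empty_series_set <- function() {
  structure(list(
    series = data.frame(as_id = integer(), core_smiles = character(),
                        n_members = integer()),
    members = data.frame(as_id = integer(), cid = character(),
                         substituent_smiles = character())),
    class = "analog_series_set")
}

#' @export
print.analog_series_set <- function(x, ...) {
  cat("<analog_series_set> ", nrow(x$series), " series, ",
      nrow(x$members), " memberships (",
      length(unique(x$members$cid)), " unique compounds)\n", sep = "")
  invisible(x)
}

#' Write / read an analog-series table
#'
#' Tab-separated series table: `as_id`, `core_smiles`, member compound ids
#' (comma-separated) and substituents (comma-separated, same order).
#'
#' @param series_set an `analog_series_set`.
#' @param path file path.
#' @return `path` (writer) or an `analog_series_set` (reader).
#' @export
write_series_table <- function(series_set, path) {
  stopifnot(inherits(series_set, "analog_series_set"))
  by_series <- split(series_set$members, series_set$members$as_id)
  rows <- vapply(seq_len(nrow(series_set$series)), function(i) {
    s <- series_set$series[i, ]
    m <- by_series[[as.character(s$as_id)]]
    paste(s$as_id, s$core_smiles,
          paste(m$cid, collapse = ","),
          paste(m$substituent_smiles, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("as_id\tcore_smiles\tcids\tsubstituents", rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_series_table
#' @export
read_series_table <- function(path) {
  if (!file.exists(path)) stop("series table not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) return(empty_series_set())
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  members <- do.call(rbind, lapply(fields, function(f) {
    if (length(f) != 4L) stop("malformed series table row", call. = FALSE)
    cids <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    subs <- strsplit(f[4], ",", fixed = TRUE)[[1]]
    if (length(cids) != length(subs)) {
      stop("cid/substituent list length mismatch for series ", f[1], call. = FALSE)
    }
    data.frame(as_id = as.integer(f[1]), cid = cids, substituent_smiles = subs)
  }))
  series <- data.frame(
    as_id = vapply(fields, function(f) as.integer(f[1]), integer(1)),
    core_smiles = vapply(fields, `[[`, character(1), 2L),
    n_members = vapply(fields, function(f)
      length(strsplit(f[3], ",", fixed = TRUE)[[1]]), integer(1)))
  structure(list(series = series, members = members),
            class = "analog_series_set")
}
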