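# Molecular descriptor backend. Scalar descriptors come from OpenBabel
# (via the obabel executable that ships with ChemmineOB's tool stack);
# aromatic-ring perception and the molecular graph for the circular
# fingerprint come from ChemmineR. "Polar surface area" is the topological
# polar surface area (TPSA).

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) abort("obabel executable not found on PATH")
  unname(p)
}

# Run obabel on a named set of SMILES, returning one row per parseable
# molecule with the requested appended descriptors.
obabel_descriptors <- function(smiles, ids) {
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(paste(smiles, ids), smi)
  out <- suppressWarnings(system2(
    obabel_path(), c(smi, "-otxt", "--append",
                     "\"MW logP TPSA HBD HBA1 HBA2 rotors\""),
    stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  if (length(out) == 0) {
    return(tibble(id = character(), mw = double(), alogp = double(),
                  tpsa = double(), hbd = integer(), hba1 = integer(),
                  hba2 = integer(), rotb = integer()))
  }
  parts <- strsplit(trimws(out), "[[:space:]]+")
  parts <- parts[lengths(parts) == 8]
  tibble(
    id = vapply(parts, `[`, character(1), 1),
    mw = as.numeric(vapply(parts, `[`, character(1), 2)),
    alogp = as.numeric(vapply(parts, `[`, character(1), 3)),
    tpsa = as.numeric(vapply(parts, `[`, character(1), 4)),
    hbd = as.integer(vapply(parts, `[`, character(1), 5)),
    hba1 = as.integer(vapply(parts, `[`, character(1), 6)),
    hba2 = as.integer(vapply(parts, `[`, character(1), 7)),
    rotb = as.integer(vapply(parts, `[`, character(1), 8))
  )
}

# Which of the named SMILES match each alert SMARTS; returns per-id count
# of distinct alert patterns matched.
obabel_alert_counts <- function(smiles, ids,
                                alerts = default_structural_alerts()) {
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(paste(smiles, ids), smi)
  counts <- setNames(integer(length(ids)), ids)
  for (i in seq_len(nrow(alerts))) {
    out <- suppressWarnings(system2(
      obabel_path(), c(smi, "-osmi", "-s", shQuote(alerts$smarts[i])),
      stdout = TRUE, stderr = FALSE))
    out <- out[nzchar(out)]
    if (length(out) == 0) next
    hit <- vapply(strsplit(out, "\t"), function(p) p[length(p)],
                  character(1))
    hit <- intersect(trimws(hit), ids)
    counts[hit] <- counts[hit] + 1L
  }
  tibble(id = ids, alerts = unname(counts))
}

#' Packaged structural-alert patterns
#'
#' A curated set of SMARTS patterns for undesirable functionality
#' (reactive, unstable or toxicophoric groups) used as the ALERTS property
#' of [weighted_qed()]. The set is an editable CSV shipped with the
#' package; it is a pragmatic curation, not a transcription of any
#' specific published alert collection.
#'
#' @return A tibble (`alert`, `smarts`).
#' @export
default_structural_alerts <- function() {
  readr::read_tsv(pkg_extdata("structural_alerts.tsv"), col_types = "cc",
                  progress = FALSE)
}

atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

# 2048-bit ECFP-style circular fingerprint (radius 2) for one ChemmineR
# SDF molecule. Initial atom invariants are (atomic number, heavy-atom
# degree, bond-order sum); two update rounds hash each atom's sorted
# (bond order, neighbour identifier) environment. Identifiers from all
# radii fold into 2048 bits. Deterministic; hydrogens are excluded.
ecfp4_bits <- function(sdf, n_bits = 2048L) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0 || is.null(rownames(ab))) {
    return(integer(0))
  }
  sym <- sub("_.*$", "", rownames(ab))
  heavy <- which(sym != "H")
  if (length(heavy) == 0) return(integer(0))
  z <- atomic_numbers[sym[heavy]]
  z[is.na(z)] <- 0

  idx <- match(seq_len(nrow(ab)), heavy)  # old atom number -> heavy index
  nb <- vector("list", length(heavy))
  ord <- vector("list", length(heavy))
  if (!is.null(bb) && nrow(bb) > 0) {
    n_atoms <- nrow(ab)
    for (k in seq_len(nrow(bb))) {
      ai <- bb[k, 1]; bi <- bb[k, 2]
      if (is.na(ai) || is.na(bi) || ai < 1 || bi < 1 ||
          ai > n_atoms || bi > n_atoms) next
      a <- idx[ai]; b <- idx[bi]
      if (is.na(a) || is.na(b)) next
      o <- bb[k, 3]
      nb[[a]] <- c(nb[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nb[[b]] <- c(nb[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  hash_vec <- function(v) {
    h <- 17
    for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
    h
  }
  deg <- lengths(nb)
  bosum <- vapply(ord, function(o) sum(o), numeric(1))
  id <- mapply(function(zz, d, bs) hash_vec(c(zz, d, bs)), z, deg, bosum)
  all_ids <- id
  for (r in 1:2) {
    id_new <- numeric(length(id))
    for (a in seq_along(id)) {
      if (deg[a] == 0) {
        id_new[a] <- hash_vec(c(r, id[a]))
      } else {
        pairs <- cbind(ord[[a]], id[nb[[a]]])
        o <- order(pairs[, 1], pairs[, 2])
        id_new[a] <- hash_vec(c(r, id[a], t(pairs[o, , drop = FALSE])))
      }
    }
    id <- id_new
    all_ids <- c(all_ids, id)
  }
  sort(unique(as.integer(all_ids %% n_bits)))
}

count_aromatic_rings <- function(sdf) {
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 10, type = "all",
                                      arom = TRUE)),
    error = function(e) NULL)
  if (is.null(r) || length(r$AROMATIC) == 0) return(0L)
  sum(r$AROMATIC)
}

#' Compute molecular descriptors from SMILES
#'
#' For each structure: molecular weight (Da), ALogP, topological polar
#' surface area (A^2), hydrogen-bond donor and acceptor counts, rotatable
#' bonds, and a 2048-bit circular fingerprint of radius 2 (ECFP4-style)
#' returned as a list-column of on-bit positions. With `extras = TRUE`
#' (needed for QED) the aromatic-ring count and structural-alert count are
#' added. Unparseable SMILES are an error under `strict = TRUE`, otherwise
#' they are dropped with a message and flagged in the `valid` attribute.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers (default `m1 ... mn`); must be unique
#'   and contain no whitespace.
#' @param fingerprint Compute the 2048-bit fingerprint list-column?
#' @param extras Compute aromatic-ring and structural-alert counts?
#' @param hba_mode `"pharmacophore"` (default; OpenBabel's refined
#'   acceptor definition) or `"n_plus_o"` (plain nitrogen+oxygen count).
#' @param strict Error on unparseable SMILES (default) or drop them.
#' @return A tibble: `id`, `smiles`, `mw`, `alogp`, `tpsa`, `hbd`, `hba`,
#'   `rotb`, plus `arom` and `alerts` when `extras`, plus list-column
#'   `fp_bits` when `fingerprint`.
#' @export
#' @examples
#' \donttest{
#' compute_descriptors("CCO", fingerprint = FALSE)
#' }
compute_descriptors <- function(smiles, ids = NULL, fingerprint = TRUE,
                                extras = FALSE,
                                hba_mode = c("pharmacophore", "n_plus_o"),
                                strict = TRUE) {
  hba_mode <- match.arg(hba_mode)
  stopifnot(length(smiles) > 0)
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  if (anyDuplicated(ids) || any(grepl("[[:space:]]", ids))) {
    abort("ids must be unique and whitespace-free")
  }

  desc <- obabel_descriptors(smiles, ids)
  bad <- setdiff(ids, desc$id)
  # obabel parses some degenerate strings to empty molecules (MW 0)
  empty <- desc$id[desc$mw <= 0]
  bad <- union(bad, empty)
  if (length(bad) > 0) {
    bad_smiles <- smiles[match(bad, ids)]
    if (strict) {
      abort(sprintf("unparseable structure(s): %s",
                    paste(head(bad_smiles, 5), collapse = ", ")))
    }
    inform(sprintf("compute_descriptors: dropped %d unparseable structure(s)",
                   length(bad)))
  }
  keep <- setdiff(ids, bad)
  desc <- desc[match(keep, desc$id), ]
  out <- tibble(
    id = desc$id,
    smiles = smiles[match(desc$id, ids)],
    mw = desc$mw, alogp = desc$alogp, tpsa = desc$tpsa,
    hbd = desc$hbd,
    hba = if (hba_mode == "pharmacophore") desc$hba2 else desc$hba1,
    rotb = desc$rotb
  )

  if ((fingerprint || extras) && nrow(out) > 0) {
    sdfset <- suppressWarnings(
      ChemmineR::smiles2sdf(setNames(out$smiles, out$id)))
    if (extras) {
      out$arom <- vapply(seq_along(sdfset), function(i)
        count_aromatic_rings(sdfset[[i]]), integer(1))
      out <- left_join(out, obabel_alert_counts(out$smiles, out$id),
                       by = "id")
    }
    if (fingerprint) {
      out$fp_bits <- lapply(seq_along(sdfset), function(i)
        ecfp4_bits(sdfset[[i]]))
    }
  }
  attr(out, "dropped") <- smiles[match(bad, ids)]
  out
}

#' Expand fingerprint list-column to a dense 0/1 matrix
#'
#' @param descriptors Output of [compute_descriptors()] with `fp_bits`.
#' @param n_bits Fingerprint length (2048).
#' @return Integer matrix, one row per molecule, `n_bits` columns.
#' @export
fingerprint_matrix <- function(descriptors, n_bits = 2048L) {
  assert_columns(descriptors, "fp_bits", "descriptors")
  m <- matrix(0L, nrow = nrow(descriptors), ncol = n_bits,
              dimnames = list(descriptors$id,
                              paste0("fp", seq_len(n_bits) - 1L)))
  for (i in seq_len(nrow(descriptors))) {
    bits <- descriptors$fp_bits[[i]]
    if (length(bits) > 0) m[i, bits + 1L] <- 1L
  }
  m
}
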