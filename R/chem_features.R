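#' Canonicalize SMILES strings
#'
#' Standardizes SMILES via Open Babel's canonical SMILES writer, so that
#' chemically equivalent encodings of the same molecule map to a single
#' string. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stop_if(!is.character(smiles) || length(smiles) == 0L,
          "`smiles` must be a non-empty character vector")
  stop_if(any(is.na(smiles) | !nzchar(smiles)),
          "`smiles` contains empty or missing entries")
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", source = s)
    out <- sub("\\s.*$", "", out)
    stop_if(!nzchar(out), "Unparsable SMILES: '", s, "'")
    out
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into a heavy-atom molecular graph: element symbols,
# bond list with orders, ring membership, and raw SDF coordinates.
smiles_to_graph <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", source = can)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  mol <- sdfset[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  symbols <- sub("_.*$", "", rownames(ab))
  n <- length(symbols)
  # single-atom/bond-free molblocks come back with degenerate blocks
  bonds <- if (n > 1 && is.matrix(bb) && ncol(bb) >= 3 && nrow(bb) > 0 &&
               all(bb[, 1] >= 1 & bb[, 1] <= n & bb[, 2] >= 1 & bb[, 2] <= n)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  coords <- matrix(0, n, 3)
  kc <- min(3L, ncol(ab))
  coords[, seq_len(kc)] <- ab[, seq_len(kc)]
  in_ring <- rep(FALSE, n)
  if (nrow(bonds) >= 3) {
    rg <- tryCatch(ChemmineR::rings(mol, type = "all", arom = FALSE),
                   error = function(e) list())
    for (ring in rg) {
      idx <- as.integer(sub("^.*_", "", ring))
      in_ring[idx] <- TRUE
    }
  }
  list(symbols = symbols, bonds = bonds, in_ring = in_ring,
       coords = coords, canonical = can)
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Computes an ECFP-style circular fingerprint: each atom's environment is
#' iteratively re-hashed from its neighbours' identifiers out to the given
#' radius, and all environment identifiers are folded into a fixed-length
#' bit vector. Deterministic and independent of atom input order (the
#' molecule is canonicalized first and neighbour identifiers are sorted
#' before hashing).
#'
#' @param smiles A single SMILES string.
#' @param radius Neighbourhood radius (number of hash iterations), >= 0.
#' @param n_bits Length of the folded bit vector, > 0.
#' @return Integer vector of 0/1 of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stop_if(length(smiles) != 1L, "`smiles` must be a single string")
  stop_if(radius < 0, "`radius` must be >= 0")
  stop_if(n_bits <= 0, "`n_bits` must be > 0")
  g <- smiles_to_graph(smiles)
  n <- length(g$symbols)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
    nbr[[a]] <- rbind(nbr[[a]], c(b, o))
    nbr[[b]] <- rbind(nbr[[b]], c(a, o))
  }
  elem <- match(g$symbols, unique(c("C", "N", "O", "S", "P", "F", "Cl",
                                    "Br", "I", "B", "Si", g$symbols)))
  degree <- vapply(nbr, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  bond_sum <- vapply(nbr, function(m) if (is.null(m)) 0L else sum(m[, 2]), integer(1))
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(elem[i], degree[i], bond_sum[i], as.integer(g$in_ring[i])))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0) {
    for (it in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        m <- nbr[[i]]
        env <- if (is.null(m)) integer(0) else {
          pairs <- cbind(m[, 2], ids[m[, 1]])
          ord <- order(pairs[, 1], pairs[, 2])
          as.vector(t(pairs[ord, , drop = FALSE]))
        }
        hash_ints(c(ids[i], env))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  bits <- integer(n_bits)
  bits[unique(all_ids %% n_bits) + 1L] <- 1L
  bits
}

# Descriptor sets available to compound_descriptors(). "basic2d" is the
# built-in lightweight 2-D set; "basic3d" adds geometric descriptors that
# require conformer coordinates and are flagged NA when none are present.
descriptor_names <- function(descriptor_set) {
  d2 <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
          "heavy_atoms", "n_bonds", "n_rings", "n_ring_atoms",
          "n_double_bonds", "n_triple_bonds", "mean_degree",
          "n_C", "n_N", "n_O", "n_S", "n_halogen", "frac_hetero")
  switch(descriptor_set,
    basic2d = d2,
    basic3d = c(d2, "radius_of_gyration", "max_interatomic_distance"),
    stop("unknown descriptor_set: '", descriptor_set,
         "' (available: basic2d, basic3d)")
  )
}

#' Physicochemical descriptors of a molecule
#'
#' Computes a fixed-length vector of 2-D molecular descriptors (Open Babel
#' properties plus graph-derived counts). The `basic3d` set appends
#' geometric descriptors; molecules without 3-D conformer coordinates get
#' `NA` for those entries rather than a silent zero.
#'
#' @param smiles A single SMILES string.
#' @param descriptor_set `"basic2d"` (default) or `"basic3d"`.
#' @return Named numeric vector; undefined descriptors are `NA`.
#' @export
compound_descriptors <- function(smiles, descriptor_set = "basic2d") {
  nms <- descriptor_names(descriptor_set)
  g <- smiles_to_graph(smiles)
  props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMI", g$canonical, identity))
  sym <- g$symbols
  deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = length(sym))
  n_rings <- 0L
  if (nrow(g$bonds) >= 3) {
    n_rings <- nrow(g$bonds) - length(sym) + 1L  # cyclomatic ring count
  }
  out <- c(
    MW = props$MW, logP = props$logP, TPSA = props$TPSA, MR = props$MR,
    HBA1 = props$HBA1, HBA2 = props$HBA2, HBD = props$HBD, nF = props$nF,
    heavy_atoms = length(sym),
    n_bonds = nrow(g$bonds),
    n_rings = n_rings,
    n_ring_atoms = sum(g$in_ring),
    n_double_bonds = sum(g$bonds$order == 2),
    n_triple_bonds = sum(g$bonds$order == 3),
    mean_degree = if (length(sym)) mean(deg) else NA_real_,
    n_C = sum(sym == "C"), n_N = sum(sym == "N"), n_O = sum(sym == "O"),
    n_S = sum(sym == "S"),
    n_halogen = sum(sym %in% c("F", "Cl", "Br", "I")),
    frac_hetero = if (length(sym)) mean(!sym %in% c("C", "H")) else NA_real_
  )
  if (descriptor_set == "basic3d") {
    xyz <- g$coords
    has_conformer <- nrow(xyz) > 1 && any(abs(xyz[, 3]) > 1e-8)
    if (has_conformer) {
      centred <- sweep(xyz, 2, colMeans(xyz))
      rg <- sqrt(mean(rowSums(centred^2)))
      dd <- as.matrix(stats::dist(xyz))
      out <- c(out, radius_of_gyration = rg,
               max_interatomic_distance = max(dd))
    } else {
      out <- c(out, radius_of_gyration = NA_real_,
               max_interatomic_distance = NA_real_)
    }
  }
  out[nms]
}

#' Drop descriptor columns containing missing values
#'
#' Mirrors the preprocessing step of discarding every descriptor that is
#' undefined (NaN/NA) for any compound, keeping column order.
#'
#' @param x Numeric matrix, compounds x descriptors.
#' @return List with `matrix` (reduced), `kept` and `dropped` column indices.
#' @export
drop_missing_descriptors <- function(x) {
  stop_if(!is.matrix(x), "`x` must be a matrix")
  ok <- colSums(is.na(x) | is.nan(x)) == 0
  stop_if(!any(ok), "every descriptor column contains missing values")
  list(matrix = x[, ok, drop = FALSE],
       kept = which(ok), dropped = which(!ok))
}

#' Random-forest selection of the top-k descriptors
#'
#' Fits one random-forest regressor per gene target and averages impurity
#' importances over targets, then keeps the k descriptors with the highest
#' mean importance (ties broken by ascending column index). The selected
#' descriptors are the ones most predictive of the expression signatures
#' the downstream model must generate.
#'
#' @param x Numeric matrix, compounds x descriptors.
#' @param y Numeric matrix, compounds x genes (aligned rows).
#' @param k Number of descriptors to keep.
#' @param seed Integer seed driving the forests.
#' @param num_trees Trees per forest.
#' @return An object of class `"feature_selector"` with elements
#'   `importance`, `selected` (ordered column indices) and `k`.
#' @export
select_top_properties <- function(x, y, k = 100L, seed = 1L, num_trees = 200L) {
  stop_if(!is.matrix(x) || !is.matrix(y), "`x` and `y` must be matrices")
  stop_if(nrow(x) != nrow(y), "`x` and `y` must have aligned rows")
  stop_if(k > ncol(x), "k = ", k, " exceeds the ", ncol(x), " descriptors")
  stop_if(k < 1, "k must be >= 1")
  xdf <- as.data.frame(x)
  names(xdf) <- paste0("f", seq_len(ncol(x)))
  imp <- matrix(0, ncol(x), ncol(y))
  for (j in seq_len(ncol(y))) {
    fit <- ranger::ranger(
      x = xdf, y = y[, j], num.trees = num_trees,
      importance = "impurity", seed = derive_seed(seed, paste0("rf", j)),
      num.threads = 1
    )
    imp[, j] <- fit$variable.importance
  }
  mean_imp <- rowMeans(imp)
  ord <- order(-mean_imp, seq_along(mean_imp))
  structure(
    list(importance = mean_imp, selected = ord[seq_len(k)], k = k,
         names = colnames(x) %||% names(xdf)),
    class = "feature_selector"
  )
}

#' @export
print.feature_selector <- function(x, ...) {
  cat("Feature selector: top", x$k, "of", length(x$importance), "descriptors\n")
  cat("Selected indices:", utils::head(x$selected, 10),
      if (x$k > 10) "..." else "", "\n")
  invisible(x)
}

#' Fit a min-max feature scaler on a reference compound set
#'
#' Learns per-feature minima and maxima on the reference set (the set the
#' downstream model is trained on), so that the reference maps into
#' \[0, 1\]. Constant features are flagged and later mapped to 0.
#'
#' @param x Reference feature matrix.
#' @return Object of class `"feature_scaler"`.
#' @export
fit_feature_scaler <- function(x) {
  stop_if(!is.matrix(x) || nrow(x) < 1, "`x` must be a non-empty matrix")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs == mins)) {
    warning("constant feature(s) at column(s) ",
            paste(which(maxs == mins), collapse = ", "),
            "; they will be mapped to 0")
  }
  structure(list(min = mins, max = maxs), class = "feature_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Values from non-reference compounds that fall outside the reference
#' range are clipped to \[0, 1\], keeping the model input domain closed.
#'
#' @param x Feature matrix with the same columns as the reference.
#' @param scaler A `"feature_scaler"`.
#' @return Scaled matrix with all entries in \[0, 1\].
#' @export
scale_features <- function(x, scaler) {
  stop_if(!inherits(scaler, "feature_scaler"), "`scaler` must be a feature_scaler")
  stop_if(ncol(x) != length(scaler$min),
          "feature count mismatch: ", ncol(x), " vs ", length(scaler$min))
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min)
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0
  pmin(pmax(out, 0), 1)
}

#' Signature strength of an expression signature
#'
#' Number of landmark genes whose absolute differential-expression value
#' meets the threshold; used to pick one representative signature per
#' compound from its many experimental conditions.
#'
#' @param signature Numeric vector of length 978.
#' @param z_threshold Absolute z-score threshold (default 2).
#' @return Integer count.
#' @export
signature_strength <- function(signature, z_threshold = 2) {
  stop_if(length(signature) != 978L,
          "signature must have length 978, got ", length(signature))
  sum(abs(signature) >= z_threshold)
}

#' Representative signature of a compound
#'
#' Among candidate signatures measured under different experimental
#' conditions, returns the one with the largest signature strength
#' (ties broken by first occurrence).
#'
#' @param candidates Matrix (candidates x 978) or list of length-978 vectors.
#' @param z_threshold Passed to [signature_strength()].
#' @return The selected length-978 numeric vector.
#' @export
representative_signature <- function(candidates, z_threshold = 2) {
  if (is.list(candidates)) {
    candidates <- do.call(rbind, candidates)
  }
  stop_if(!is.matrix(candidates) || nrow(candidates) < 1,
          "`candidates` must contain at least one signature")
  ss <- apply(candidates, 1, signature_strength, z_threshold = z_threshold)
  candidates[which.max(ss), ]
}

#' Build the full feature matrix for a compound table
#'
#' Convenience wrapper: canonicalizes SMILES, computes Morgan fingerprints
#' and descriptors for every compound, and returns the two blocks.
#'
#' @param compounds Data frame with columns `compound_id` and `smiles`.
#' @param radius,n_bits Fingerprint parameters.
#' @param descriptor_set Passed to [compound_descriptors()].
#' @return List with matrices `fingerprints` and `descriptors`, rownames
#'   set to `compound_id`.
#' @export
featurize_compounds <- function(compounds, radius = 2L, n_bits = 2048L,
                                descriptor_set = "basic2d") {
  stop_if(!all(c("compound_id", "smiles") %in% names(compounds)),
          "`compounds` needs columns compound_id and smiles")
  fps <- t(vapply(compounds$smiles, morgan_fingerprint,
                  integer(n_bits), radius = radius, n_bits = n_bits))
  desc <- t(vapply(compounds$smiles, compound_descriptors,
                   numeric(length(descriptor_names(descriptor_set))),
                   descriptor_set = descriptor_set))
  rownames(fps) <- rownames(desc) <- compounds$compound_id
  list(fingerprints = fps, descriptors = desc)
}

#' Read / write expression signature matrices as GCT-like TSV
#'
#' Plain-text matrix format: first column `compound_id`, remaining columns
#' one per landmark gene, tab-separated with a header row.
#'
#' @param path File path.
#' @return `read_signatures` returns a numeric matrix with compound
#'   rownames and gene colnames.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "compound_id", "first column must be compound_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$compound_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_signatures
#' @param x Numeric matrix, compounds x genes.
#' @export
write_signatures <- function(x, path) {
  df <- data.frame(compound_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore fitted preprocessing artifacts as JSON
#'
#' Feature scalers and selectors are plain-text artifacts so a featurization
#' run can be reproduced elsewhere.
#'
#' @param x A `"feature_scaler"` or `"feature_selector"`.
#' @param path Output path.
#' @export
save_artifact <- function(x, path) {
  stop_if(!inherits(x, c("feature_scaler", "feature_selector")),
          "unsupported artifact class")
  payload <- c(list(.class = class(x)[1]), unclass(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (cls == "feature_selector") {
    payload$selected <- as.integer(payload$selected)
    payload$k <- as.integer(payload$k)
  }
  structure(payload, class = cls)
}
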