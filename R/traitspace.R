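#' Gower dissimilarity matrix for mixed traits
#'
#' Computes the Gower dissimilarity over a declared trait subset: numeric
#' traits contribute `|x - y| / range`, categorical traits contribute a 0/1
#' mismatch indicator, and the per-pair dissimilarity is the unweighted mean
#' over traits (via [cluster::daisy()]). Constant traits have an undefined
#' range term and are dropped with a warning.
#'
#' @param table Trait tibble (no missing values; run [impute_traits()]
#'   first).
#' @param traits Character vector of trait columns to use; default: every
#'   non-identity column.
#' @param schema Optional `"trait_schema"` declaring categorical levels.
#' @return A symmetric dissimilarity matrix in `[0, 1]` with species ids as
#'   dimnames.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   species_id = c("a", "b"), trophic_level = "resource", taxon_group = "g",
#'   size = c(1, 3), colour = c("red", "white")
#' )
#' gower_matrix(tab) # (1 + 1) / 2 = 1 off-diagonal
gower_matrix <- function(table, traits = NULL, schema = NULL) {
  if (nrow(table) < 2) stop_data("need >= 2 species for a dissimilarity matrix")
  if (is.null(schema)) schema <- attr(table, "schema") %||% infer_schema(table)
  traits <- traits %||% names(schema)
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr)) {
    stop_key(sprintf("trait(s) not in table: %s",
                     paste(missing_tr, collapse = ", ")))
  }
  df <- as.data.frame(table[traits])
  if (anyNA(df)) {
    stop_data("missing trait values; impute before computing dissimilarities")
  }
  for (cl in traits) {
    if (!is.numeric(df[[cl]])) {
      lv <- if (cl %in% names(schema)) schema[[cl]]$levels else NULL
      df[[cl]] <- factor(df[[cl]], levels = lv %||% sort(unique(df[[cl]])))
    }
  }
  constant <- vapply(df, function(v) length(unique(v)) == 1L, logical(1))
  if (all(constant)) {
    stop_data("all traits are constant; trait space is degenerate")
  }
  if (any(constant)) {
    warn(sprintf("dropping constant trait(s): %s",
                 paste(traits[constant], collapse = ", ")))
    df <- df[!constant]
  }
  d <- as.matrix(cluster::daisy(df, metric = "gower"))
  dimnames(d) <- list(table$species_id, table$species_id)
  d
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Embeds a dissimilarity matrix in Euclidean coordinates: square-root
#' transform of the dissimilarities (the standard correction making Gower
#' matrices near-Euclidean), double-centering of the squared distances,
#' eigendecomposition, and retention of `min(m_max, #positive eigenvalues)`
#' axes scaled by the square root of their eigenvalues. A warning is raised
#' when the residual negative eigenvalue mass exceeds 5% of the total
#' absolute mass.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param m_max Maximum number of retained axes (default 4).
#' @param sqrt_correction Apply the square-root transform first? Set `FALSE`
#'   for dissimilarities that are already Euclidean distances.
#' @return An object of class `"trait_space"`: `ids`, `coordinates`
#'   (n x m matrix), `eigenvalues` (all, descending), `m`, `stress`
#'   (relative distance-reconstruction error), `sqrt_correction`.
#' @export
pcoa <- function(d, m_max = 4, sqrt_correction = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop_data("need >= 2 species for an ordination")
  ids <- rownames(d) %||% as.character(seq_len(n))
  D <- if (sqrt_correction) sqrt(d) else d
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  tol <- 1e-10 * max(abs(ev))
  n_pos <- sum(ev > tol)
  if (n_pos == 0) stop_data("no positive eigenvalues; degenerate trait space")
  neg_mass <- sum(abs(ev[ev < -tol])) / sum(abs(ev))
  if (neg_mass > 0.05) {
    warn(sprintf(
      "negative eigenvalue mass %.1f%% remains after correction; axes truncated",
      100 * neg_mass
    ))
  }
  m <- min(m_max, n_pos)
  coords <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m)
  rownames(coords) <- ids
  colnames(coords) <- paste0("axis_", seq_len(m))
  recon <- as.matrix(dist(coords))
  stress <- sqrt(sum((recon - D)^2) / sum(D^2))
  structure(
    list(ids = ids, coordinates = coords, eigenvalues = ev, m = m,
         stress = stress, sqrt_correction = sqrt_correction,
         global_volume = hull_volume(coords)),
    class = "trait_space"
  )
}

#' Build a trait space directly from a trait table
#'
#' Convenience pipeline: [gower_matrix()] then [pcoa()]. One trait space is
#' built per trophic level and shared by every hull computed at that level,
#' so volumes are comparable across species and communities.
#'
#' @inheritParams gower_matrix
#' @inheritParams pcoa
#' @return A `"trait_space"`.
#' @export
trait_space <- function(table, traits = NULL, m_max = 4, schema = NULL) {
  pcoa(gower_matrix(table, traits = traits, schema = schema), m_max = m_max)
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf(
    "<trait_space> %d species, %d axes (stress %.3g, sqrt correction: %s)\n",
    length(x$ids), x$m, x$stress, x$sqrt_correction
  ))
  invisible(x)
}

#' @method as_tibble trait_space
#' @export
as_tibble.trait_space <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(species_id = x$ids),
                   tibble::as_tibble(x$coordinates))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Standardized functional richness of a species subset
#'
#' Functional richness (FRic) of `member_ids` relative to a reference set:
#' the convex-hull volume of the members in the trait-space axes divided by
#' the hull volume of `global_ids` (by default, all species at the level) in
#' the same axes. The ratio lies in `[0, 1]`: 1 means the members span the
#' full reference trait space. Member sets that cannot support an
#' m-dimensional hull (fewer than m + 1 members, or affinely dependent) get
#' FRic 0 with the `"degenerate"` attribute set, so a single scale of
#' m-dimensional volumes is never mixed with lower-dimensional ones.
#'
#' @param member_ids Character vector of member species ids (may be empty).
#' @param space A `"trait_space"` containing all ids.
#' @param global_ids Reference set; defaults to every species in `space`.
#' @return A single value in `[0, 1]` with attributes `degenerate` (logical)
#'   and `volume` (raw hull volume of the members).
#' @export
fric_standardized <- function(member_ids, space, global_ids = space$ids) {
  unknown <- setdiff(c(member_ids, global_ids), space$ids)
  if (length(unknown)) {
    stop_key(sprintf("unknown species id(s): %s",
                     paste(head(unknown, 5), collapse = ", ")))
  }
  if (!all(member_ids %in% global_ids)) {
    stop_key("member_ids must be a subset of global_ids")
  }
  gvol <- if (setequal(global_ids, space$ids) &&
                !is.null(space$global_volume)) {
    space$global_volume
  } else {
    hull_volume(space$coordinates[global_ids, , drop = FALSE])
  }
  if (attr(gvol, "degenerate")) {
    stop_data("reference set spans no volume in the trait space")
  }
  vol <- hull_volume(space$coordinates[unique(member_ids), , drop = FALSE])
  val <- if (attr(vol, "degenerate")) 0 else min(1, as.numeric(vol) / as.numeric(gvol))
  structure(val, degenerate = attr(vol, "degenerate"),
            volume = as.numeric(vol))
}
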