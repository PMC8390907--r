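#' Cubic periodic simulation box
#'
#' A cubic, periodic box of edge length `edge_length` Angstrom. The
#' temperature is carried as metadata only (no energetics are computed
#' anywhere in the package).
#'
#' @param edge_length box edge in Angstrom; must be > 0.
#' @param temperature temperature label in Kelvin (metadata, default 298).
#' @return an object of class `box_spec` with elements `edge_length`,
#'   `periodic` (always TRUE), `temperature`.
#' @examples
#' b <- box_spec(60)
#' box_volume(b)  # 216000 A^3
#' @export
box_spec <- function(edge_length, temperature = 298) {
  if (!is.numeric(edge_length) || length(edge_length) != 1L ||
      !is.finite(edge_length) || edge_length <= 0)
    stop("edge_length must be a single positive number (Angstrom)")
  structure(list(edge_length = as.numeric(edge_length), periodic = TRUE,
                 temperature = temperature),
            class = "box_spec")
}

#' @rdname box_spec
#' @param box a `box_spec`.
#' @export
box_volume <- function(box) box$edge_length^3

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("Cubic periodic box: L = %.3f A (V = %.1f A^3), T = %s K\n",
              x$edge_length, box_volume(x), format(x$temperature)))
  invisible(x)
}

.roster_roles <- c("water", "cation", "anion", "protein_heavy",
                   "protein_hydrogen")

#' Species roster for synthetic systems
#'
#' Describes which species populate a synthetic box: a label (used to select
#' atoms later), a particle count and a role. When `electroneutral = TRUE`
#' the total cation and anion counts must match.
#'
#' @param label character vector of species labels.
#' @param count integer vector of particle counts (>= 0).
#' @param role character vector; each element one of `r toString(.roster_roles)`.
#' @param electroneutral require equal cation and anion totals (default TRUE
#'   when both roles are present).
#' @return a `data.frame` of class `species_roster`.
#' @examples
#' species_roster(c("K", "ACE"), c(500, 500), c("cation", "anion"))
#' @export
species_roster <- function(label, count, role,
                           electroneutral = NULL) {
  if (length(label) != length(count) || length(label) != length(role))
    stop("label, count and role must have equal length")
  if (anyDuplicated(label)) stop("species labels must be unique")
  count <- as.integer(count)
  if (any(is.na(count)) || any(count < 0)) stop("counts must be >= 0")
  if (!all(role %in% .roster_roles))
    stop("unknown role; must be one of: ", toString(.roster_roles))
  n_plus <- sum(count[role == "cation"])
  n_minus <- sum(count[role == "anion"])
  if (is.null(electroneutral)) electroneutral <- n_plus > 0 && n_minus > 0
  if (electroneutral && n_plus != n_minus)
    stop("electroneutral roster requires equal cation and anion counts")
  out <- data.frame(label = as.character(label), count = count,
                    role = as.character(role), stringsAsFactors = FALSE)
  class(out) <- c("species_roster", "data.frame")
  attr(out, "electroneutral") <- electroneutral
  out
}

#' Total ion count of a roster (cosolvent convention)
#'
#' The cosolvent treatment of a 1:1 electrolyte counts cations and anions as
#' one indistinguishable species: n_c = n_+ + n_-.
#'
#' @param roster a `species_roster`.
#' @return integer total ion count.
#' @export
ion_count <- function(roster) {
  sum(roster$count[roster$role %in% c("cation", "anion")])
}

#' Crystallographic contact-site table
#'
#' Table of cation contact sites at a protein surface: residue number and
#' name, the coordinating (carboxylate) oxygen name and the crystallographic
#' cation-oxygen distance `r_cryst` in Angstrom.
#'
#' @param site_id integer or character site identifiers.
#' @param resnum residue numbers.
#' @param resname residue names (e.g. "ASP", "GLU").
#' @param atom coordinating oxygen atom names.
#' @param r_cryst_A crystallographic contact distances in Angstrom (> 0).
#' @return a `data.frame` of class `contact_site_table`.
#' @export
contact_site_table <- function(site_id, resnum, resname, atom, r_cryst_A) {
  if (any(r_cryst_A <= 0)) stop("r_cryst must be > 0")
  out <- data.frame(site_id = site_id, resnum = as.integer(resnum),
                    resname = as.character(resname), atom = as.character(atom),
                    r_cryst_A = as.numeric(r_cryst_A),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_site_table", "data.frame")
  out
}

#' @rdname contact_site_table
#' @param x a `contact_site_table`.
#' @param file path to a CSV file.
#' @export
write_contact_table <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname contact_site_table
#' @export
read_contact_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  contact_site_table(d$site_id, d$resnum, d$resname, d$atom, d$r_cryst_A)
}
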