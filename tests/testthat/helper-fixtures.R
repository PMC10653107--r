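# Memoized model fixtures: ground states and dense eigendecompositions are
# cached on the determinant space, so sharing fixture objects across tests
# avoids repeating the expensive solves.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, zeta = NULL, twice_ms = NULL) {
  key <- paste(name, format(zeta), format(twice_ms), sep = "|")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- model_fixture(name, zeta = zeta,
                                         twice_ms = twice_ms)
  .fixture_env[[key]]
}

get_ground_state <- function(fx, ...) {
  key <- paste0("gs_", fx$ints$id)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- ground_state(fx$ints, fx$space, ...)
  .fixture_env[[key]]
}

# two-level absorber: one electron in two orbitals, transition energy
# `delta` (eV) and moment `m` (a.u.) on the x component
two_level_ints <- function(delta = 10, m = 0.8) {
  space <- orbital_space(c("g", "e"), c("RAS2", "RAS2"),
                         c("valence", "valence"))
  h1 <- diag(c(0, ev_to_hartree(delta)))
  dip <- list(x = matrix(c(0, m, m, 0), 2, 2), y = matrix(0, 2, 2),
              z = matrix(0, 2, 2))
  integral_set(space, h1 = h1, dip = dip)
}

# three-level RIXS ladder: ground (orb 1), core-excited intermediate
# (orb 2, energy e2), valence-excited final (orb 3, energy e3); x couples
# 1<->2 (absorption), y couples 2<->3 (emission)
three_level_ints <- function(e2 = 700, e3 = 2, m1 = 0.9, m2 = 0.6) {
  space <- orbital_space(c("g", "c", "f"), rep("RAS2", 3),
                         c("valence", "core", "valence"))
  h1 <- diag(ev_to_hartree(c(0, e2, e3)))
  z <- matrix(0, 3, 3)
  dx <- z; dx[1, 2] <- dx[2, 1] <- m1
  dy <- z; dy[2, 3] <- dy[3, 2] <- m2
  integral_set(space, h1 = h1, dip = list(x = dx, y = dy, z = z))
}
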