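# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# small synthetic hemipelvis (V = 642) for cheap unit tests
small_template <- function() fixture("small_template", function() make_template(2L))

# full-size template (V = 2562) used where resolution matters
big_template <- function() fixture("big_template", function() make_template(3L))

# a 40-shape population and 15-component model on the big template
big_model <- function() fixture("big_model", function() {
  tpl <- big_template()
  pop <- generate_population(tpl$mesh, population_spec(
    n_shapes = 40L, n_modes = 3L, mode_stddevs = c(6, 3, 1.5), seed = 7L))
  model <- build_model(pop$meshes, n_components = 15L, template = tpl$mesh)
  list(model = model, pop = pop, template = tpl)
})

# unit tetrahedron (positively oriented)
tetrahedron <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tet")
}

# axis-aligned unit cube as 12 triangles, outward-oriented
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangle_mesh(v, f, name = "cube")
}

# icosphere of unit radius at the given subdivision level
unit_sphere <- function(level = 3L) {
  ico <- ssmrec:::icosphere(level)
  triangle_mesh(ico$vertices, ico$faces, name = "sphere")
}

# rotation matrix about z by deg
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
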