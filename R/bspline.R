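# Cubic B-spline displacement-field machinery shared by the synthetic
# deformation generator and the deformable registration. A field is
# parameterized by a 4D coefficient array (mx, my, mz, 3) on a control grid
# with spacing `cp_spacing` (mm) that pads the image domain by one knot on
# each side so every image point has full 4-knot support.

bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Control-point layout covering [origin, origin + (dim-1)*spacing] per axis.
control_layout <- function(geom, cp_spacing) {
  lapply(1:3, function(ax) {
    lo <- geom$origin[ax]
    hi <- geom$origin[ax] + (geom$dim[ax] - 1) * geom$spacing[ax]
    s <- cp_spacing[if (length(cp_spacing) == 3) ax else 1]
    first <- lo - s
    m <- ceiling((hi - first) / s) + 2
    list(first = first, spacing = s, m = as.integer(m))
  })
}

# Basis matrix (length(coords) x m) for one axis.
basis_matrix <- function(coords, layout) {
  centers <- layout$first + (seq_len(layout$m) - 1) * layout$spacing
  outer(coords, centers, function(x, c) bspline3((x - c) / layout$spacing))
}

# Contract the first dimension of `arr` with `mat` (out[i,..] = sum_a mat[i,a] arr[a,..]).
contract_first <- function(arr, mat) {
  d <- dim(arr)
  array(mat %*% matrix(arr, d[1], prod(d[-1])), c(nrow(mat), d[-1]))
}

# Separable tensor product: out[i,j,k] = sum_{abc} Bx[i,a] By[j,b] Bz[k,c] C[a,b,c].
tensor3 <- function(C, Bx, By, Bz) {
  out <- contract_first(C, Bx)                  # (nx, my, mz)
  out <- aperm(out, c(2, 3, 1))
  out <- contract_first(out, By)                # (ny, mz, nx)
  out <- aperm(out, c(2, 3, 1))
  out <- contract_first(out, Bz)                # (nz, nx, ny)
  aperm(out, c(2, 3, 1))
}

# Evaluate a coefficient array (mx,my,mz,3) as a displacement_field on `geom`.
bspline_field <- function(coefs, layouts, geom) {
  Bx <- basis_matrix(axis_coords(geom, 1), layouts[[1]])
  By <- basis_matrix(axis_coords(geom, 2), layouts[[2]])
  Bz <- basis_matrix(axis_coords(geom, 3), layouts[[3]])
  vals <- array(0, c(geom$dim, 3))
  for (k in 1:3) vals[, , , k] <- tensor3(coefs[, , , k], Bx, By, Bz)
  displacement_field(vals, geom$spacing, geom$origin)
}

# Adjoint of tensor3: project a voxel array onto the control grid.
tensor3_adjoint <- function(G, Bx, By, Bz) tensor3(G, t(Bx), t(By), t(Bz))
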