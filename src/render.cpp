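// Per-pixel rendering passes: sphere-impostor rasterization, max-depth
// pyramid, multiscale SSAO, screen-space contact shadows, and exact
// back-to-front transparency compositing. Scalar double arithmetic
// throughout, no threading, so identical inputs give bit-identical
// rasters.
//
// Conventions (shared with the R side): camera at the view-space origin
// looking along +z(view); x right, y up in view space; pixel (0,0) is the
// top-left corner, pixel centers at (+0.5, +0.5); depth is the axial
// view-space distance mapped linearly to [0,1] between near and far;
// background depth is 1 and object id -1. Stored normals are view-space
// unit vectors; a surface facing the camera has negative z.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Cam {
  double px, py, pz;      // world position
  double rx, ry, rz;      // right
  double ux, uy, uz;      // true up
  double fx, fy, fz;      // forward
  double fpix, nearp, farp;
  int W, H;
};

static Cam make_cam(NumericVector pos, NumericVector right, NumericVector up,
                    NumericVector fwd, double fpix, double nearp,
                    double farp, int W, int H) {
  Cam c;
  c.px = pos[0]; c.py = pos[1]; c.pz = pos[2];
  c.rx = right[0]; c.ry = right[1]; c.rz = right[2];
  c.ux = up[0]; c.uy = up[1]; c.uz = up[2];
  c.fx = fwd[0]; c.fy = fwd[1]; c.fz = fwd[2];
  c.fpix = fpix; c.nearp = nearp; c.farp = farp; c.W = W; c.H = H;
  return c;
}

// [[Rcpp::export(name = "cpp_rasterize")]]
List cpp_rasterize(NumericMatrix centers, NumericVector radii,
                   IntegerVector obj_id, NumericVector sphere_rgb,
                   NumericVector pos, NumericVector right, NumericVector up,
                   NumericVector fwd, double fpix, double nearp, double farp,
                   int W, int H, int mode, NumericVector light,
                   double ambient) {
  Cam cam = make_cam(pos, right, up, fwd, fpix, nearp, farp, W, H);
  const int n = centers.nrow();
  NumericMatrix depth(H, W), nxm(H, W), nym(H, W), nzm(H, W);
  IntegerMatrix oid(H, W);
  NumericVector colorR(H * W), colorG(H * W), colorB(H * W);
  std::fill(depth.begin(), depth.end(), 1.0);
  std::fill(oid.begin(), oid.end(), -1);
  const double zrange = cam.farp - cam.nearp;
  const double lx = light[0], ly = light[1], lz = light[2];

  for (int i = 0; i < n; ++i) {
    const double wx = centers(i, 0) - cam.px;
    const double wy = centers(i, 1) - cam.py;
    const double wz = centers(i, 2) - cam.pz;
    const double cx = wx * cam.rx + wy * cam.ry + wz * cam.rz;
    const double cy = wx * cam.ux + wy * cam.uy + wz * cam.uz;
    const double cz = wx * cam.fx + wy * cam.fy + wz * cam.fz;
    const double r = radii[i];
    if (cz + r < cam.nearp) continue;         // fully behind near plane
    if (cz - r > cam.farp) continue;          // fully beyond far plane

    int x0, x1, y0, y1;
    if (cz - r <= cam.nearp) {                // conservatively full image
      x0 = 0; x1 = W - 1; y0 = 0; y1 = H - 1;
    } else {
      double sxmin = 1e30, sxmax = -1e30, symin = 1e30, symax = -1e30;
      for (int k = 0; k < 8; ++k) {
        const double X = cx + ((k & 1) ? r : -r);
        const double Y = cy + ((k & 2) ? r : -r);
        const double Z = cz + ((k & 4) ? r : -r);
        const double sx = W * 0.5 + cam.fpix * X / Z;
        const double sy = H * 0.5 - cam.fpix * Y / Z;
        sxmin = std::min(sxmin, sx); sxmax = std::max(sxmax, sx);
        symin = std::min(symin, sy); symax = std::max(symax, sy);
      }
      x0 = std::max(0, (int)std::floor(sxmin) - 1);
      x1 = std::min(W - 1, (int)std::ceil(sxmax) + 1);
      y0 = std::max(0, (int)std::floor(symin) - 1);
      y1 = std::min(H - 1, (int)std::ceil(symax) + 1);
      if (x0 > x1 || y0 > y1) continue;
    }
    const double c2r2 = cx * cx + cy * cy + cz * cz - r * r;

    for (int py = y0; py <= y1; ++py) {
      for (int px = x0; px <= x1; ++px) {
        const double vx = (px + 0.5 - W * 0.5) / cam.fpix;
        const double vy = (H * 0.5 - (py + 0.5)) / cam.fpix;
        const double L = std::sqrt(vx * vx + vy * vy + 1.0);
        const double ux_ = vx / L, uy_ = vy / L, uz_ = 1.0 / L;
        const double b = ux_ * cx + uy_ * cy + uz_ * cz;
        const double disc = b * b - c2r2;
        if (disc < 0) continue;
        const double sq = std::sqrt(disc);
        double t = b - sq;
        if (t < 0) { t = b + sq; if (t < 0) continue; }
        const double zax = t * uz_;           // axial hit depth
        if (zax < cam.nearp || zax > cam.farp) continue;
        double d01;
        double nx, ny, nz;
        if (mode == 0) {                      // exact ray-cast impostor
          d01 = (zax - cam.nearp) / zrange;
          nx = (t * ux_ - cx) / r; ny = (t * uy_ - cy) / r;
          nz = (t * uz_ - cz) / r;
        } else if (mode == 1) {               // approximate: front depth,
          d01 = (cz - r - cam.nearp) / zrange;  // disc-parameterized normal
          const double qx = (b * ux_ - cx) / r;
          const double qy = (b * uy_ - cy) / r;
          const double q2 = qx * qx + qy * qy;
          const double qz = -std::sqrt(std::max(0.0, 1.0 - q2));
          nx = qx; ny = qy; nz = qz;
        } else {                              // flat disc at center depth
          d01 = (cz - cam.nearp) / zrange;
          nx = 0; ny = 0; nz = -1;
        }
        if (d01 < 0) d01 = 0; if (d01 > 1) d01 = 1;
        if (d01 < depth(py, px)) {            // strict <: earlier index wins ties
          depth(py, px) = d01;
          oid(py, px) = obj_id[i];
          nxm(py, px) = nx; nym(py, px) = ny; nzm(py, px) = nz;
          const double lam = std::max(0.0, nx * lx + ny * ly + nz * lz);
          const double sh = ambient + (1.0 - ambient) * lam;
          const int idx = py + H * px;
          colorR[idx] = sphere_rgb[i] * sh;
          colorG[idx] = sphere_rgb[i + n] * sh;
          colorB[idx] = sphere_rgb[i + 2 * n] * sh;
        }
      }
    }
  }
  return List::create(_["depth"] = depth, _["oid"] = oid,
                      _["nx"] = nxm, _["ny"] = nym, _["nz"] = nzm,
                      _["r"] = colorR, _["g"] = colorG, _["b"] = colorB);
}

// [[Rcpp::export(name = "cpp_depth_pyramid")]]
List cpp_depth_pyramid(NumericMatrix depth) {
  int H = depth.nrow(), W = depth.ncol();
  int maxdim = std::max(W, H);
  int nlev = 1 + (int)std::floor(std::log2((double)maxdim));
  List out(nlev);
  out[0] = depth;
  NumericMatrix prev = depth;
  for (int l = 1; l < nlev; ++l) {
    int h2 = (prev.nrow() + 1) / 2, w2 = (prev.ncol() + 1) / 2;
    NumericMatrix cur(h2, w2);
    for (int y = 0; y < h2; ++y) {
      for (int x = 0; x < w2; ++x) {
        double m = -1.0;
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            int yy = 2 * y + dy, xx = 2 * x + dx;
            if (yy < prev.nrow() && xx < prev.ncol())
              m = std::max(m, prev(yy, xx));
          }
        cur(y, x) = m;
      }
    }
    out[l] = cur;
    prev = cur;
  }
  return out;
}

// [[Rcpp::export(name = "cpp_ssao")]]
NumericMatrix cpp_ssao(NumericMatrix depth, IntegerMatrix oid,
                       NumericMatrix nxm, NumericMatrix nym,
                       NumericMatrix nzm, double fpix, double nearp,
                       double farp, NumericVector radii,
                       NumericMatrix kernel, double strength, double bias) {
  // kernel: nsamp x 3 unit-hemisphere directions (z >= 0), with
  // per-sample length jitter already applied on the R side.
  const int H = depth.nrow(), W = depth.ncol();
  const int nsamp = kernel.nrow(), nscale = radii.size();
  const double zrange = farp - nearp;
  NumericMatrix occ(H, W);
  for (int py = 0; py < H; ++py) {
    for (int px = 0; px < W; ++px) {
      if (oid(py, px) < 0) { occ(py, px) = 0.0; continue; }
      const double zax = nearp + depth(py, px) * zrange;
      const double X = (px + 0.5 - W * 0.5) * zax / fpix;
      const double Y = (H * 0.5 - (py + 0.5)) * zax / fpix;
      // outward normal (toward the camera side): stored normal has
      // negative z for camera-facing surfaces; hemisphere axis = -n? No:
      // the stored normal IS the outward surface normal in view space.
      double nx = nxm(py, px), ny = nym(py, px), nz = nzm(py, px);
      // tangent frame
      double ax = 1, ay = 0, az = 0;
      if (std::fabs(nx) > 0.9) { ax = 0; ay = 1; }
      double tx = ay * nz - az * ny, ty = az * nx - ax * nz,
             tz = ax * ny - ay * nx;
      double tl = std::sqrt(tx * tx + ty * ty + tz * tz);
      tx /= tl; ty /= tl; tz /= tl;
      double bx = ny * tz - nz * ty, by = nz * tx - nx * tz,
             bz = nx * ty - ny * tx;
      double total = 0.0;
      for (int s = 0; s < nscale; ++s) {
        const double R = radii[s];
        int hit = 0;
        for (int k = 0; k < nsamp; ++k) {
          const double kx = kernel(k, 0), ky = kernel(k, 1), kz = kernel(k, 2);
          const double sx = X + R * (tx * kx + bx * ky + nx * kz);
          const double sy = Y + R * (ty * kx + by * ky + ny * kz);
          const double sz = zax + R * (tz * kx + bz * ky + nz * kz);
          if (sz < nearp) continue;
          const int ix = (int)std::floor(W * 0.5 + fpix * sx / sz);
          const int iy = (int)std::floor(H * 0.5 - fpix * sy / sz);
          if (ix < 0 || ix >= W || iy < 0 || iy >= H) continue;
          if (oid(iy, ix) < 0) continue;
          const double bz_ax = nearp + depth(iy, ix) * zrange;
          // occluded: recorded geometry in front of the sample, within
          // range (avoids halos from distant silhouettes)
          if (bz_ax < sz - bias && (sz - bz_ax) < 2.0 * R) hit++;
        }
        total += (double)hit / (double)nsamp;
      }
      occ(py, px) = total / (double)nscale;
    }
  }
  // ambient factor
  NumericMatrix fac(H, W);
  for (int i = 0; i < H * W; ++i) {
    double f = 1.0 - strength * occ[i];
    fac[i] = std::max(0.0, std::min(1.0, f));
  }
  return fac;
}

// [[Rcpp::export(name = "cpp_bilateral")]]
NumericMatrix cpp_bilateral(NumericMatrix img, NumericMatrix depth,
                            int radius, double depth_sigma) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double inv2s2 = 1.0 / (2.0 * depth_sigma * depth_sigma);
  for (int py = 0; py < H; ++py) {
    for (int px = 0; px < W; ++px) {
      const double d0 = depth(py, px);
      double acc = 0, wsum = 0;
      for (int dy = -radius; dy <= radius; ++dy) {
        for (int dx = -radius; dx <= radius; ++dx) {
          const int y = py + dy, x = px + dx;
          if (x < 0 || x >= W || y < 0 || y >= H) continue;
          const double dd = depth(y, x) - d0;
          const double w = std::exp(-dd * dd * inv2s2);
          acc += w * img(y, x);
          wsum += w;
        }
      }
      out(py, px) = acc / wsum;
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_contact_shadows")]]
NumericMatrix cpp_contact_shadows(NumericMatrix depth, IntegerMatrix oid,
                                  double fpix, double nearp, double farp,
                                  NumericVector light, int steps,
                                  double max_frac, double bias,
                                  double strength) {
  const int H = depth.nrow(), W = depth.ncol();
  const double zrange = farp - nearp;
  const double lx = light[0], ly = light[1], lz = light[2];
  const double diag = std::sqrt((double)(W * W + H * H));
  NumericMatrix fac(H, W);
  std::fill(fac.begin(), fac.end(), 1.0);
  for (int py = 0; py < H; ++py) {
    for (int px = 0; px < W; ++px) {
      if (oid(py, px) < 0) continue;
      const double zax = nearp + depth(py, px) * zrange;
      const double X = (px + 0.5 - W * 0.5) * zax / fpix;
      const double Y = (H * 0.5 - (py + 0.5)) * zax / fpix;
      // view-space step sized so the first projected step moves about
      // (max_frac * diag / steps) pixels
      const double world_per_px = zax / fpix;
      const double step_len = max_frac * diag / steps * world_per_px;
      bool shadowed = false;
      for (int s = 1; s <= steps; ++s) {
        const double sx = X + lx * step_len * s;
        const double sy = Y + ly * step_len * s;
        const double sz = zax + lz * step_len * s;
        if (sz < nearp) break;                // marched in front of near plane
        const int ix = (int)std::floor(W * 0.5 + fpix * sx / sz);
        const int iy = (int)std::floor(H * 0.5 - fpix * sy / sz);
        if (ix < 0 || ix >= W || iy < 0 || iy >= H) break;
        if (oid(iy, ix) < 0) continue;
        const double bz_ax = nearp + depth(iy, ix) * zrange;
        const double sd01 = (sz - nearp) / zrange;
        const double bd01 = depth(iy, ix);
        // the marched ray is deeper than what the camera sees there:
        // something lies between this pixel and the light
        if (sd01 - bd01 > bias) { shadowed = true; break; }
        (void)bz_ax;
      }
      if (shadowed) fac(py, px) = std::max(0.0, 1.0 - strength);
    }
  }
  return fac;
}

// Transparent sphere fragments composited back-to-front over a base
// image. alpha_eff = alpha_group * clamp(n.v, 0, 1)^gamma with n the hit
// normal and v the direction from the hit point to the camera.
// [[Rcpp::export(name = "cpp_composite_transparent")]]
List cpp_composite_transparent(NumericVector baseR, NumericVector baseG,
                               NumericVector baseB, NumericMatrix opaque_depth,
                               NumericMatrix centers, NumericVector radii,
                               NumericVector alpha, NumericVector gamma_,
                               NumericVector sphere_rgb, NumericVector pos,
                               NumericVector right, NumericVector up,
                               NumericVector fwd, double fpix, double nearp,
                               double farp, int W, int H,
                               NumericVector light, double ambient) {
  Cam cam = make_cam(pos, right, up, fwd, fpix, nearp, farp, W, H);
  const int n = centers.nrow();
  const double zrange = cam.farp - cam.nearp;
  const double lx = light[0], ly = light[1], lz = light[2];
  struct Frag { double d, r, g, b, a; };
  std::vector<std::vector<Frag> > frags((size_t)W * H);
  for (int i = 0; i < n; ++i) {
    const double wx = centers(i, 0) - cam.px;
    const double wy = centers(i, 1) - cam.py;
    const double wz = centers(i, 2) - cam.pz;
    const double cx = wx * cam.rx + wy * cam.ry + wz * cam.rz;
    const double cy = wx * cam.ux + wy * cam.uy + wz * cam.uz;
    const double cz = wx * cam.fx + wy * cam.fy + wz * cam.fz;
    const double r = radii[i];
    if (cz + r < cam.nearp || cz - r > cam.farp) continue;
    int x0 = 0, x1 = W - 1, y0 = 0, y1 = H - 1;
    if (cz - r > cam.nearp) {
      double sxmin = 1e30, sxmax = -1e30, symin = 1e30, symax = -1e30;
      for (int k = 0; k < 8; ++k) {
        const double X = cx + ((k & 1) ? r : -r);
        const double Y = cy + ((k & 2) ? r : -r);
        const double Z = cz + ((k & 4) ? r : -r);
        const double sx = W * 0.5 + cam.fpix * X / Z;
        const double sy = H * 0.5 - cam.fpix * Y / Z;
        sxmin = std::min(sxmin, sx); sxmax = std::max(sxmax, sx);
        symin = std::min(symin, sy); symax = std::max(symax, sy);
      }
      x0 = std::max(0, (int)std::floor(sxmin) - 1);
      x1 = std::min(W - 1, (int)std::ceil(sxmax) + 1);
      y0 = std::max(0, (int)std::floor(symin) - 1);
      y1 = std::min(H - 1, (int)std::ceil(symax) + 1);
      if (x0 > x1 || y0 > y1) continue;
    }
    const double c2r2 = cx * cx + cy * cy + cz * cz - r * r;
    for (int py = y0; py <= y1; ++py) {
      for (int px = x0; px <= x1; ++px) {
        const double vx = (px + 0.5 - W * 0.5) / cam.fpix;
        const double vy = (H * 0.5 - (py + 0.5)) / cam.fpix;
        const double L = std::sqrt(vx * vx + vy * vy + 1.0);
        const double ux_ = vx / L, uy_ = vy / L, uz_ = 1.0 / L;
        const double b = ux_ * cx + uy_ * cy + uz_ * cz;
        const double disc = b * b - c2r2;
        if (disc < 0) continue;
        const double sq = std::sqrt(disc);
        double t = b - sq;
        if (t < 0) { t = b + sq; if (t < 0) continue; }
        const double zax = t * uz_;
        if (zax < cam.nearp || zax > cam.farp) continue;
        const double d01 = std::max(0.0, std::min(1.0, (zax - cam.nearp) / zrange));
        if (d01 >= opaque_depth(py, px)) continue;  // hidden behind opaque
        const double nx = (t * ux_ - cx) / r, ny = (t * uy_ - cy) / r,
                     nz = (t * uz_ - cz) / r;
        const double ndv = std::max(0.0, std::min(1.0,
                              -(nx * ux_ + ny * uy_ + nz * uz_)));
        const double aeff = alpha[i] * std::pow(ndv, gamma_[i]);
        if (aeff <= 0) continue;
        const double lam = std::max(0.0, nx * lx + ny * ly + nz * lz);
        const double sh = ambient + (1.0 - ambient) * lam;
        Frag f;
        f.d = d01;
        f.r = sphere_rgb[i] * sh; f.g = sphere_rgb[i + n] * sh;
        f.b = sphere_rgb[i + 2 * n] * sh; f.a = aeff;
        frags[(size_t)py + (size_t)H * px].push_back(f);
      }
    }
  }
  NumericVector outR = clone(baseR), outG = clone(baseG), outB = clone(baseB);
  for (size_t p = 0; p < frags.size(); ++p) {
    std::vector<Frag> &v = frags[p];
    if (v.empty()) continue;
    std::stable_sort(v.begin(), v.end(),
                     [](const Frag &a, const Frag &b) { return a.d > b.d; });
    double cr = outR[p], cg = outG[p], cb = outB[p];
    for (size_t k = 0; k < v.size(); ++k) {  // back-to-front "over"
      cr = v[k].r * v[k].a + cr * (1.0 - v[k].a);
      cg = v[k].g * v[k].a + cg * (1.0 - v[k].a);
      cb = v[k].b * v[k].a + cb * (1.0 - v[k].a);
    }
    outR[p] = std::min(1.0, cr); outG[p] = std::min(1.0, cg);
    outB[p] = std::min(1.0, cb);
  }
  return List::create(_["r"] = outR, _["g"] = outG, _["b"] = outB);
}
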