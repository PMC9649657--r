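// Compiled core: restraint energy terms with analytic gradients, the
// velocity-Verlet integrator with adaptive timestep, Gaussian map simulation,
// masked real-space cross-correlation, and the coarse rigid-body docking scan.
// Units: kcal/mol, Angstrom, amu, ps, radians internally.

#include <RcppArmadillo.h>
#include <unordered_set>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KB = 0.0019872041;   // kcal/mol/K
static const double FCONV = 418.4;       // kcal/mol == FCONV * amu A^2/ps^2

struct MapCtx {
  std::vector<double> grid;      // target map values (full grid)
  int nx, ny, nz;
  double ox, oy, oz, voxel, sigma, cutoff;
  std::vector<int> mask;         // linear voxel indices (0-based)
  std::vector<char> inmask;      // full-grid boolean
  std::vector<double> tb;        // target minus mask-mean, per mask voxel
  std::vector<int> mask_pos;     // full grid -> position in mask (-1 if absent)
  double sbb;                    // sum tb^2
};

struct Ctx {
  int natom;
  // bonds
  std::vector<int> b_i, b_j; std::vector<double> b_r0; double k_bond = 0;
  // angles
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0; double k_angle = 0;
  // impropers
  std::vector<int> im_i, im_j, im_k, im_l; std::vector<double> im_t0; double k_impr = 0;
  // dihedral restraints
  std::vector<int> dh_i, dh_j, dh_k, dh_l;
  std::vector<double> dh_tgt, dh_tol; double k_dih = 0;
  // distance restraints (flattened ambiguous pairs)
  std::vector<int> dr_pi, dr_pj, dr_off; // dr_off length R+1
  std::vector<double> dr_lo, dr_hi; double k_dist = 0;
  // NCS
  std::vector<std::vector<int>> ncs_idx; double k_ncs = 0, ncs_tol = 1.0;
  // map term
  bool has_map = false; MapCtx map; std::vector<int> map_sel; double k_map = 0;
  // repulsion
  double k_repel = 0, r_repel = 2.0;
  std::unordered_set<long long> excl;
  // radius of gyration
  double k_rgyr = 0, rgyr_target = 0;
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Ctx build_ctx(const List& spec, int natom) {
  Ctx c; c.natom = natom;
  if (spec.containsElementNamed("bonds")) {
    IntegerMatrix b = spec["bonds"]; NumericVector r0 = spec["bond_r0"];
    c.k_bond = as<double>(spec["k_bond"]);
    for (int m = 0; m < b.nrow(); ++m) {
      c.b_i.push_back(b(m,0)); c.b_j.push_back(b(m,1)); c.b_r0.push_back(r0[m]);
    }
  }
  if (spec.containsElementNamed("angles")) {
    IntegerMatrix a = spec["angles"]; NumericVector t0 = spec["angle_t0"];
    c.k_angle = as<double>(spec["k_angle"]);
    for (int m = 0; m < a.nrow(); ++m) {
      c.a_i.push_back(a(m,0)); c.a_j.push_back(a(m,1)); c.a_k.push_back(a(m,2));
      c.a_t0.push_back(t0[m]);
    }
  }
  if (spec.containsElementNamed("impropers")) {
    IntegerMatrix im = spec["impropers"]; NumericVector t0 = spec["impr_t0"];
    c.k_impr = as<double>(spec["k_impr"]);
    for (int m = 0; m < im.nrow(); ++m) {
      c.im_i.push_back(im(m,0)); c.im_j.push_back(im(m,1));
      c.im_k.push_back(im(m,2)); c.im_l.push_back(im(m,3));
      c.im_t0.push_back(t0[m]);
    }
  }
  if (spec.containsElementNamed("dihres")) {
    IntegerMatrix d = spec["dihres"];
    NumericVector tg = spec["dih_target"], tl = spec["dih_tol"];
    c.k_dih = as<double>(spec["k_dih"]);
    for (int m = 0; m < d.nrow(); ++m) {
      c.dh_i.push_back(d(m,0)); c.dh_j.push_back(d(m,1));
      c.dh_k.push_back(d(m,2)); c.dh_l.push_back(d(m,3));
      c.dh_tgt.push_back(tg[m]); c.dh_tol.push_back(tl[m]);
    }
  }
  if (spec.containsElementNamed("dr_pairs")) {
    IntegerMatrix p = spec["dr_pairs"]; IntegerVector off = spec["dr_offset"];
    NumericVector lo = spec["dr_lower"], hi = spec["dr_upper"];
    c.k_dist = as<double>(spec["k_dist"]);
    for (int m = 0; m < p.nrow(); ++m) { c.dr_pi.push_back(p(m,0)); c.dr_pj.push_back(p(m,1)); }
    for (int m = 0; m < off.size(); ++m) c.dr_off.push_back(off[m]);
    for (int m = 0; m < lo.size(); ++m) { c.dr_lo.push_back(lo[m]); c.dr_hi.push_back(hi[m]); }
  }
  if (spec.containsElementNamed("ncs_idx")) {
    IntegerMatrix ni = spec["ncs_idx"];
    c.k_ncs = as<double>(spec["k_ncs"]); c.ncs_tol = as<double>(spec["ncs_tol"]);
    for (int s = 0; s < ni.nrow(); ++s) {
      std::vector<int> v(ni.ncol());
      for (int m = 0; m < ni.ncol(); ++m) v[m] = ni(s,m);
      c.ncs_idx.push_back(v);
    }
  }
  if (spec.containsElementNamed("map")) {
    List mp = spec["map"];
    NumericVector g = mp["grid"]; IntegerVector dims = mp["dims"];
    NumericVector orig = mp["origin"];
    c.map.nx = dims[0]; c.map.ny = dims[1]; c.map.nz = dims[2];
    c.map.ox = orig[0]; c.map.oy = orig[1]; c.map.oz = orig[2];
    c.map.voxel = as<double>(mp["voxel"]);
    c.map.sigma = as<double>(mp["sigma"]);
    c.map.cutoff = as<double>(mp["cutoff"]);
    c.map.grid.assign(g.begin(), g.end());
    IntegerVector mk = mp["mask"];
    c.map.mask.assign(mk.begin(), mk.end());
    size_t ngrid = c.map.grid.size();
    c.map.inmask.assign(ngrid, 0);
    c.map.mask_pos.assign(ngrid, -1);
    for (size_t t = 0; t < c.map.mask.size(); ++t) {
      c.map.inmask[c.map.mask[t]] = 1;
      c.map.mask_pos[c.map.mask[t]] = (int)t;
    }
    double tmean = 0;
    for (int v : c.map.mask) tmean += c.map.grid[v];
    tmean /= (double)c.map.mask.size();
    c.map.tb.resize(c.map.mask.size());
    c.map.sbb = 0;
    for (size_t t = 0; t < c.map.mask.size(); ++t) {
      c.map.tb[t] = c.map.grid[c.map.mask[t]] - tmean;
      c.map.sbb += c.map.tb[t] * c.map.tb[t];
    }
    IntegerVector sel = spec["map_sel"];
    c.map_sel.assign(sel.begin(), sel.end());
    c.has_map = true;
    c.k_map = as<double>(spec["k_map"]);
  }
  if (spec.containsElementNamed("k_repel")) {
    c.k_repel = as<double>(spec["k_repel"]);
    c.r_repel = as<double>(spec["r_repel"]);
    if (spec.containsElementNamed("excl")) {
      IntegerMatrix ex = spec["excl"];
      for (int m = 0; m < ex.nrow(); ++m)
        c.excl.insert(pkey(ex(m,0), ex(m,1), natom));
    }
  }
  if (spec.containsElementNamed("k_rgyr")) {
    c.k_rgyr = as<double>(spec["k_rgyr"]);
    c.rgyr_target = as<double>(spec["rgyr_target"]);
  }
  return c;
}

// ---- geometric primitives -------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0]=a[0]-b[0]; out[1]=a[1]-b[1]; out[2]=a[2]-b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0]*b[0]+a[1]*b[1]+a[2]*b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0]=a[1]*b[2]-a[2]*b[1]; out[1]=a[2]*b[0]-a[0]*b[2]; out[2]=a[0]*b[1]-a[1]*b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a,a)); }

// dihedral angle (rad) for points p1-p2-p3-p4 and gradient wrt each point
// (standard analytic torsion derivative)
static double dihedral_grad(const double* p1, const double* p2,
                            const double* p3, const double* p4,
                            double* g1, double* g2, double* g3, double* g4,
                            bool want_grad) {
  double b1[3], b2[3], b3[3];
  vsub(p2, p1, b1); vsub(p3, p2, b2); vsub(p4, p3, b3);
  double n1[3], n2[3];
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double nb2 = vnorm(b2);
  double m1[3]; vcross(n1, b2, m1);
  double x = vdot(n1, n2), y = vdot(m1, n2) / nb2;
  double phi = std::atan2(y, x);
  if (want_grad) {
    double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
    if (n1sq < 1e-12 || n2sq < 1e-12) {
      for (int k=0;k<3;++k) { g1[k]=g2[k]=g3[k]=g4[k]=0; }
      return phi;
    }
    // dphi/dr under this atan2 sign convention (verified against finite
    // differences): g1 = |b2|/|m|^2 m, g4 = -|b2|/|n|^2 n,
    // g2 = -(1+p) g1 + q g4, g3 = p g1 - (1+q) g4
    double f1[3], f4[3];
    for (int k=0;k<3;++k) {
      f1[k] =  nb2 / n1sq * n1[k];
      f4[k] = -nb2 / n2sq * n2[k];
    }
    double p = vdot(b1, b2) / (nb2*nb2);
    double q = vdot(b3, b2) / (nb2*nb2);
    for (int k=0;k<3;++k) {
      g1[k] = f1[k];
      g2[k] = -(1.0 + p) * f1[k] + q * f4[k];
      g3[k] = p * f1[k] - (1.0 + q) * f4[k];
      g4[k] = f4[k];
    }
  }
  return phi;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2*M_PI;
  while (x <= -M_PI) x += 2*M_PI;
  return x;
}

// ---- energy evaluation ----------------------------------------------------

struct EnergyOut {
  double bond=0, angle=0, improper=0, dihres=0, distres=0, ncs=0, map=0,
         repel=0, rgyr=0;
  double total() const {
    return bond+angle+improper+dihres+distres+ncs+map+repel+rgyr;
  }
};

static EnergyOut eval_energy(const Ctx& c, const double* X, double* G,
                             bool want_grad) {
  EnergyOut e;
  int n = c.natom;
  if (want_grad) std::fill(G, G + 3*n, 0.0);

  // bonds: k (r - r0)^2
  for (size_t m = 0; m < c.b_i.size(); ++m) {
    const double *pi = X + 3*c.b_i[m], *pj = X + 3*c.b_j[m];
    double d[3]; vsub(pi, pj, d);
    double r = vnorm(d);
    if (r < 1e-9) continue;
    double dev = r - c.b_r0[m];
    e.bond += c.k_bond * dev * dev;
    if (want_grad) {
      double f = 2.0 * c.k_bond * dev / r;
      for (int k=0;k<3;++k) {
        G[3*c.b_i[m]+k] += f * d[k];
        G[3*c.b_j[m]+k] -= f * d[k];
      }
    }
  }

  // angles: k (theta - t0)^2, theta in rad
  for (size_t m = 0; m < c.a_i.size(); ++m) {
    const double *pi = X + 3*c.a_i[m], *pj = X + 3*c.a_j[m], *pk = X + 3*c.a_k[m];
    double rij[3], rkj[3];
    vsub(pi, pj, rij); vsub(pk, pj, rkj);
    double nij = vnorm(rij), nkj = vnorm(rkj);
    if (nij < 1e-9 || nkj < 1e-9) continue;
    double cs = vdot(rij, rkj) / (nij*nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dev = th - c.a_t0[m];
    e.angle += c.k_angle * dev * dev;
    if (want_grad) {
      // floor keeps forces bounded when an angle passes through linearity
      double sn = std::sqrt(std::max(1e-8, 1.0 - cs*cs));
      double coef = -2.0 * c.k_angle * dev / sn;
      for (int k=0;k<3;++k) {
        double di = (rkj[k]/(nij*nkj) - cs*rij[k]/(nij*nij));
        double dk = (rij[k]/(nij*nkj) - cs*rkj[k]/(nkj*nkj));
        G[3*c.a_i[m]+k] += coef * di;
        G[3*c.a_k[m]+k] += coef * dk;
        G[3*c.a_j[m]+k] -= coef * (di + dk);
      }
    }
  }

  // impropers: k wrap(phi - t0)^2
  double g1[3], g2[3], g3[3], g4[3];
  for (size_t m = 0; m < c.im_i.size(); ++m) {
    double phi = dihedral_grad(X+3*c.im_i[m], X+3*c.im_j[m],
                               X+3*c.im_k[m], X+3*c.im_l[m],
                               g1, g2, g3, g4, want_grad);
    double dev = wrap_pi(phi - c.im_t0[m]);
    e.improper += c.k_impr * dev * dev;
    if (want_grad) {
      double f = 2.0 * c.k_impr * dev;
      for (int k=0;k<3;++k) {
        G[3*c.im_i[m]+k] += f*g1[k]; G[3*c.im_j[m]+k] += f*g2[k];
        G[3*c.im_k[m]+k] += f*g3[k]; G[3*c.im_l[m]+k] += f*g4[k];
      }
    }
  }

  // dihedral restraints: k max(0, |wrap(phi - tgt)| - tol)^2
  for (size_t m = 0; m < c.dh_i.size(); ++m) {
    double phi = dihedral_grad(X+3*c.dh_i[m], X+3*c.dh_j[m],
                               X+3*c.dh_k[m], X+3*c.dh_l[m],
                               g1, g2, g3, g4, want_grad);
    double dev = wrap_pi(phi - c.dh_tgt[m]);
    double excess = std::fabs(dev) - c.dh_tol[m];
    if (excess > 0) {
      e.dihres += c.k_dih * excess * excess;
      if (want_grad) {
        double f = 2.0 * c.k_dih * excess * (dev > 0 ? 1.0 : -1.0);
        for (int k=0;k<3;++k) {
          G[3*c.dh_i[m]+k] += f*g1[k]; G[3*c.dh_j[m]+k] += f*g2[k];
          G[3*c.dh_k[m]+k] += f*g3[k]; G[3*c.dh_l[m]+k] += f*g4[k];
        }
      }
    }
  }

  // distance restraints: flat-bottom quadratic on r^-6-summed effective distance
  int nres = (int)c.dr_off.size() - 1;
  for (int r = 0; r < nres; ++r) {
    int p0 = c.dr_off[r], p1 = c.dr_off[r+1];
    double s6 = 0;
    std::vector<double> rr(p1-p0);
    for (int p = p0; p < p1; ++p) {
      const double *pi = X + 3*c.dr_pi[p], *pj = X + 3*c.dr_pj[p];
      double d[3]; vsub(pi, pj, d);
      double rp = std::max(1e-6, vnorm(d));
      rr[p-p0] = rp;
      s6 += std::pow(rp, -6.0);
    }
    double deff = std::pow(s6, -1.0/6.0);
    double dev = 0;
    if (deff > c.dr_hi[r]) dev = deff - c.dr_hi[r];
    else if (deff < c.dr_lo[r]) dev = deff - c.dr_lo[r];
    if (dev != 0) {
      e.distres += c.k_dist * dev * dev;
      if (want_grad) {
        // dE/ddeff, ddeff/drp = (deff/rp)^7 per pair
        double dEdd = 2.0 * c.k_dist * dev;
        for (int p = p0; p < p1; ++p) {
          double rp = rr[p-p0];
          double dd_drp = std::pow(deff / rp, 7.0);
          const double *pi = X + 3*c.dr_pi[p], *pj = X + 3*c.dr_pj[p];
          double d[3]; vsub(pi, pj, d);
          double f = dEdd * dd_drp / rp;
          for (int k=0;k<3;++k) {
            G[3*c.dr_pi[p]+k] += f * d[k];
            G[3*c.dr_pj[p]+k] -= f * d[k];
          }
        }
      }
    }
  }

  // NCS: per subunit pair, Kabsch-superpose then penalize RMSD excess over tol
  if (c.k_ncs > 0 && c.ncs_idx.size() >= 2) {
    int nsub = (int)c.ncs_idx.size();
    int m = (int)c.ncs_idx[0].size();
    for (int a = 0; a < nsub; ++a) for (int b = a+1; b < nsub; ++b) {
      arma::mat P(m,3), Q(m,3);
      for (int t = 0; t < m; ++t) for (int k=0;k<3;++k) {
        P(t,k) = X[3*c.ncs_idx[a][t]+k];
        Q(t,k) = X[3*c.ncs_idx[b][t]+k];
      }
      arma::rowvec cp = arma::mean(P,0), cq = arma::mean(Q,0);
      P.each_row() -= cp; Q.each_row() -= cq;
      arma::mat H = Q.t() * P;   // rotate Q onto P
      arma::mat U, V; arma::vec s;
      arma::svd(U, s, V, H);
      double dsign = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
      arma::mat D = arma::eye(3,3); D(2,2) = dsign;
      arma::mat R = V * D * U.t();
      arma::mat Qr = Q * R.t();
      arma::mat diff = P - Qr;
      double msd = arma::accu(diff % diff) / m;
      double rmsd = std::sqrt(std::max(0.0, msd));
      double excess = rmsd - c.ncs_tol;
      if (excess > 0) {
        e.ncs += c.k_ncs * excess * excess;
        if (want_grad && rmsd > 1e-9) {
          // envelope theorem: rotation/translation optimal, so treat fixed
          double f = 2.0 * c.k_ncs * excess / rmsd / m;
          arma::mat gP = f * diff;           // d rmsd^2 / dP * scaling
          arma::mat gQ = -f * (diff * R);    // chain through Qr = Q R^T
          // centering: gradients of the means cancel since colSums(diff)=0
          for (int t = 0; t < m; ++t) for (int k=0;k<3;++k) {
            G[3*c.ncs_idx[a][t]+k] += gP(t,k);
            G[3*c.ncs_idx[b][t]+k] += gQ(t,k);
          }
        }
      }
    }
  }

  // map term: k (1 - CC), simulated Gaussian density of selected atoms vs target
  if (c.has_map && c.k_map > 0 && !c.map_sel.empty()) {
    const MapCtx& M = c.map;
    size_t nm = M.mask.size();
    std::vector<double> s(nm, 0.0);
    double inv2s2 = 1.0 / (2.0 * M.sigma * M.sigma);
    double cut2 = M.cutoff * M.cutoff;
    int span = (int)std::ceil(M.cutoff / M.voxel);
    for (int ai : c.map_sel) {
      const double* p = X + 3*ai;
      int cx = (int)std::floor((p[0]-M.ox)/M.voxel);
      int cy = (int)std::floor((p[1]-M.oy)/M.voxel);
      int cz = (int)std::floor((p[2]-M.oz)/M.voxel);
      for (int iz = std::max(0,cz-span); iz <= std::min(M.nz-1,cz+span); ++iz)
      for (int iy = std::max(0,cy-span); iy <= std::min(M.ny-1,cy+span); ++iy)
      for (int ix = std::max(0,cx-span); ix <= std::min(M.nx-1,cx+span); ++ix) {
        int lin = ix + M.nx*(iy + M.ny*iz);
        int mp = M.mask_pos[lin];
        if (mp < 0) continue;
        double dx = M.ox + ix*M.voxel - p[0];
        double dy = M.oy + iy*M.voxel - p[1];
        double dz = M.oz + iz*M.voxel - p[2];
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 > cut2) continue;
        s[mp] += std::exp(-r2 * inv2s2);
      }
    }
    double smean = 0;
    for (double v : s) smean += v;
    smean /= (double)nm;
    double saa = 0, sab = 0;
    for (size_t t = 0; t < nm; ++t) {
      double a = s[t] - smean;
      saa += a*a; sab += a * M.tb[t];
    }
    if (saa < 1e-12) stop("structure density does not overlap the map (out-of-map)");
    double denom = std::sqrt(saa * M.sbb);
    double cc = sab / denom;
    e.map = c.k_map * (1.0 - cc);
    if (want_grad) {
      // dCC/ds_t = (tb_t - (sab/saa) a_t) / denom ; chain through Gaussians
      double r1 = 1.0/denom, r2f = sab/(saa*denom);
      for (int ai : c.map_sel) {
        const double* p = X + 3*ai;
        int cx = (int)std::floor((p[0]-M.ox)/M.voxel);
        int cy = (int)std::floor((p[1]-M.oy)/M.voxel);
        int cz = (int)std::floor((p[2]-M.oz)/M.voxel);
        double gx=0, gy=0, gz=0;
        for (int iz = std::max(0,cz-span); iz <= std::min(M.nz-1,cz+span); ++iz)
        for (int iy = std::max(0,cy-span); iy <= std::min(M.ny-1,cy+span); ++iy)
        for (int ix = std::max(0,cx-span); ix <= std::min(M.nx-1,cx+span); ++ix) {
          int lin = ix + M.nx*(iy + M.ny*iz);
          int mp = M.mask_pos[lin];
          if (mp < 0) continue;
          double dx = M.ox + ix*M.voxel - p[0];
          double dy = M.oy + iy*M.voxel - p[1];
          double dz = M.oz + iz*M.voxel - p[2];
          double r2 = dx*dx+dy*dy+dz*dz;
          if (r2 > cut2) continue;
          double g = std::exp(-r2 * inv2s2);
          double dccds = r1*M.tb[mp] - r2f*(s[mp]-smean);
          // ds/dp = g * (voxpos - p) * ... derivative of exp(-r^2/2s^2) wrt p
          double coef = dccds * g * 2.0 * inv2s2;
          gx += coef * dx; gy += coef * dy; gz += coef * dz;
        }
        // E = k(1-CC) -> dE/dp = -k dCC/dp
        G[3*ai+0] -= c.k_map * gx;
        G[3*ai+1] -= c.k_map * gy;
        G[3*ai+2] -= c.k_map * gz;
      }
    }
  }

  // soft-sphere repulsion below r_repel, excluding bonded (1-2/1-3) pairs
  if (c.k_repel > 0) {
    double r0 = c.r_repel, r02 = r0*r0;
    for (int i = 0; i < n; ++i) for (int j = i+1; j < n; ++j) {
      double d[3]; vsub(X+3*i, X+3*j, d);
      if (std::fabs(d[0]) > r0 || std::fabs(d[1]) > r0 || std::fabs(d[2]) > r0)
        continue;
      double r2 = vdot(d,d);
      if (r2 >= r02 || r2 < 1e-12) continue;
      if (c.excl.count(pkey(i,j,n))) continue;
      double r = std::sqrt(r2);
      double dev = r0 - r;
      e.repel += c.k_repel * dev * dev;
      if (want_grad) {
        double f = -2.0 * c.k_repel * dev / r;
        for (int k=0;k<3;++k) {
          G[3*i+k] += f * d[k];
          G[3*j+k] -= f * d[k];
        }
      }
    }
  }

  // weak radius-of-gyration restraint (gyration-volume surrogate)
  if (c.k_rgyr > 0) {
    double cx=0, cy=0, cz=0;
    for (int i=0;i<n;++i) { cx+=X[3*i]; cy+=X[3*i+1]; cz+=X[3*i+2]; }
    cx/=n; cy/=n; cz/=n;
    double s2 = 0;
    for (int i=0;i<n;++i) {
      double dx=X[3*i]-cx, dy=X[3*i+1]-cy, dz=X[3*i+2]-cz;
      s2 += dx*dx+dy*dy+dz*dz;
    }
    double rg = std::sqrt(s2/n);
    double dev = rg - c.rgyr_target;
    e.rgyr = c.k_rgyr * dev * dev;
    if (want_grad && rg > 1e-9) {
      double f = 2.0 * c.k_rgyr * dev / (rg * n);
      for (int i=0;i<n;++i) {
        G[3*i+0] += f*(X[3*i]-cx);
        G[3*i+1] += f*(X[3*i+1]-cy);
        G[3*i+2] += f*(X[3*i+2]-cz);
      }
    }
  }

  return e;
}

static List energy_to_list(const EnergyOut& e, NumericMatrix* grad) {
  NumericVector terms = NumericVector::create(
    _["bond"] = e.bond, _["angle"] = e.angle, _["improper"] = e.improper,
    _["dihedral"] = e.dihres, _["distance"] = e.distres, _["ncs"] = e.ncs,
    _["map"] = e.map, _["repel"] = e.repel, _["rgyr"] = e.rgyr);
  List out = List::create(_["terms"] = terms, _["total"] = e.total());
  if (grad) out["gradient"] = *grad;
  return out;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, List spec, bool want_grad = true) {
  int n = coords.nrow();
  Ctx c = build_ctx(spec, n);
  std::vector<double> X(3*n), G(3*n, 0.0);
  for (int i=0;i<n;++i) for (int k=0;k<3;++k) X[3*i+k] = coords(i,k);
  EnergyOut e = eval_energy(c, X.data(), G.data(), want_grad);
  if (want_grad) {
    NumericMatrix gm(n, 3);
    for (int i=0;i<n;++i) for (int k=0;k<3;++k) gm(i,k) = G[3*i+k];
    return energy_to_list(e, &gm);
  }
  return energy_to_list(e, nullptr);
}

// ---- dynamics -------------------------------------------------------------

// Velocity-Verlet with velocity-rescaling thermostat, adaptive timestep
// (halved on energy-conservation breach, relaxed back), optional fixed atoms
// and one rigid group integrated with 6 rigid degrees of freedom.
// [[Rcpp::export]]
List cpp_dynamics(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
                  List spec, IntegerVector free_idx, IntegerVector rigid_idx,
                  double temperature, double duration_ps, int max_steps,
                  double dt0_fs, double econs_frac = 0.02,
                  int rescale_every = 10, bool thermostat = true) {
  int n = coords.nrow();
  Ctx c = build_ctx(spec, n);
  std::vector<double> X(3*n), V(3*n), G(3*n);
  for (int i=0;i<n;++i) for (int k=0;k<3;++k) {
    X[3*i+k] = coords(i,k); V[3*i+k] = vel(i,k);
  }
  std::vector<int> fr(free_idx.begin(), free_idx.end());
  std::vector<int> rg(rigid_idx.begin(), rigid_idx.end());
  bool has_rigid = !rg.empty();

  // rigid-body state
  double rM = 0, rcom[3] = {0,0,0}, rv[3] = {0,0,0}, romega[3] = {0,0,0};
  if (has_rigid) {
    for (int i : rg) {
      rM += mass[i];
      for (int k=0;k<3;++k) rcom[k] += mass[i]*X[3*i+k];
    }
    for (int k=0;k<3;++k) rcom[k] /= rM;
  }

  double dt = dt0_fs * 1e-3;            // ps
  const double dtmin = 0.1e-3, dt0 = dt0_fs * 1e-3;
  int ndof = 3*(int)fr.size() + (has_rigid ? 6 : 0);
  if (ndof <= 0) stop("no mobile degrees of freedom");

  EnergyOut e = eval_energy(c, X.data(), G.data(), true);
  double epot = e.total();

  auto kinetic = [&]() {
    double ek = 0;
    for (int i : fr) ek += 0.5 * mass[i] *
      (V[3*i]*V[3*i] + V[3*i+1]*V[3*i+1] + V[3*i+2]*V[3*i+2]);
    if (has_rigid) {
      ek += 0.5 * rM * (rv[0]*rv[0]+rv[1]*rv[1]+rv[2]*rv[2]);
      // rotational KE with instantaneous inertia tensor
      double I[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int i : rg) {
        double d[3] = {X[3*i]-rcom[0], X[3*i+1]-rcom[1], X[3*i+2]-rcom[2]};
        double r2 = vdot(d,d);
        for (int a=0;a<3;++a) for (int b=0;b<3;++b)
          I[a][b] += mass[i] * ((a==b ? r2 : 0.0) - d[a]*d[b]);
      }
      double Iw[3];
      for (int a=0;a<3;++a) Iw[a] = I[a][0]*romega[0]+I[a][1]*romega[1]+I[a][2]*romega[2];
      ek += 0.5 * vdot(romega, Iw);
    }
    return ek / FCONV;                   // kcal/mol
  };

  auto rigid_force = [&](double* F, double* tau) {
    F[0]=F[1]=F[2]=tau[0]=tau[1]=tau[2]=0;
    for (int i : rg) {
      double f[3] = {-G[3*i], -G[3*i+1], -G[3*i+2]};
      double d[3] = {X[3*i]-rcom[0], X[3*i+1]-rcom[1], X[3*i+2]-rcom[2]};
      double t[3]; vcross(d, f, t);
      for (int k=0;k<3;++k) { F[k]+=f[k]; tau[k]+=t[k]; }
    }
  };

  auto apply_rigid_motion = [&](const double* dr, const double* axis_angle) {
    double th = vnorm(axis_angle);
    double Rm[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    if (th > 1e-12) {
      double u[3] = {axis_angle[0]/th, axis_angle[1]/th, axis_angle[2]/th};
      double ct = std::cos(th), st = std::sin(th);
      for (int a=0;a<3;++a) for (int b=0;b<3;++b) {
        double K = (a==0&&b==1)?-u[2]:(a==0&&b==2)?u[1]:(a==1&&b==0)?u[2]:
                   (a==1&&b==2)?-u[0]:(a==2&&b==0)?-u[1]:(a==2&&b==1)?u[0]:0;
        Rm[a][b] = (a==b?ct:0) + st*K + (1-ct)*u[a]*u[b];
      }
    }
    for (int i : rg) {
      double d[3] = {X[3*i]-rcom[0], X[3*i+1]-rcom[1], X[3*i+2]-rcom[2]};
      double nd[3];
      for (int a=0;a<3;++a)
        nd[a] = Rm[a][0]*d[0]+Rm[a][1]*d[1]+Rm[a][2]*d[2];
      for (int a=0;a<3;++a) X[3*i+a] = rcom[a] + nd[a] + dr[a];
    }
    for (int k=0;k<3;++k) rcom[k] += dr[k];
  };

  int nsteps = 0, nhalve = 0, since_halve = 0, stuck = 0;
  double t = 0;
  bool failed = false;
  double etot_prev = epot + kinetic();

  while (t < duration_ps && nsteps < max_steps) {
    // half-kick + drift
    for (int i : fr) {
      double am = FCONV / mass[i];
      for (int k=0;k<3;++k) {
        V[3*i+k] += 0.5 * dt * (-G[3*i+k]) * am;
        X[3*i+k] += dt * V[3*i+k];
      }
    }
    if (has_rigid) {
      double F[3], tau[3];
      rigid_force(F, tau);
      // inertia tensor (world frame)
      double I[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int i : rg) {
        double d[3] = {X[3*i]-rcom[0], X[3*i+1]-rcom[1], X[3*i+2]-rcom[2]};
        double r2 = vdot(d,d);
        for (int a=0;a<3;++a) for (int b=0;b<3;++b)
          I[a][b] += mass[i] * ((a==b ? r2 : 0.0) - d[a]*d[b]);
      }
      arma::mat Im(3,3);
      for (int a=0;a<3;++a) for (int b=0;b<3;++b) Im(a,b) = I[a][b];
      arma::vec tv = {tau[0], tau[1], tau[2]};
      arma::vec wdot = arma::solve(Im, tv) * FCONV;
      for (int k=0;k<3;++k) {
        rv[k] += 0.5 * dt * F[k] * FCONV / rM;
        romega[k] += 0.5 * dt * wdot(k);
      }
      double dr[3] = {dt*rv[0], dt*rv[1], dt*rv[2]};
      double aa[3] = {dt*romega[0], dt*romega[1], dt*romega[2]};
      apply_rigid_motion(dr, aa);
    }

    e = eval_energy(c, X.data(), G.data(), true);
    epot = e.total();

    // second half-kick
    for (int i : fr) {
      double am = FCONV / mass[i];
      for (int k=0;k<3;++k) V[3*i+k] += 0.5 * dt * (-G[3*i+k]) * am;
    }
    if (has_rigid) {
      double F[3], tau[3];
      rigid_force(F, tau);
      double I[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (int i : rg) {
        double d[3] = {X[3*i]-rcom[0], X[3*i+1]-rcom[1], X[3*i+2]-rcom[2]};
        double r2 = vdot(d,d);
        for (int a=0;a<3;++a) for (int b=0;b<3;++b)
          I[a][b] += mass[i] * ((a==b ? r2 : 0.0) - d[a]*d[b]);
      }
      arma::mat Im(3,3);
      for (int a=0;a<3;++a) for (int b=0;b<3;++b) Im(a,b) = I[a][b];
      arma::vec tv = {tau[0], tau[1], tau[2]};
      arma::vec wdot = arma::solve(Im, tv) * FCONV;
      for (int k=0;k<3;++k) {
        rv[k] += 0.5 * dt * F[k] * FCONV / rM;
        romega[k] += 0.5 * dt * wdot(k);
      }
    }

    double etot = epot + kinetic();
    if (!std::isfinite(etot)) { failed = true; break; }
    double scale = std::max(std::fabs(etot_prev), 10.0);
    if (std::fabs(etot - etot_prev) > econs_frac * scale) {
      if (dt <= dtmin * 1.0001) {
        if (++stuck > 50) { failed = true; break; }
      } else {
        dt = std::max(dtmin, dt * 0.5);
        ++nhalve; since_halve = 0;
      }
    } else {
      stuck = 0;
      if (++since_halve >= 100 && dt < dt0) {
        dt = std::min(dt0, dt * 1.5);
        since_halve = 0;
      }
    }
    etot_prev = etot;

    // thermostat: velocity rescaling of the free atoms only; a rigid group
    // is driven by forces alone so it cannot be kicked out of its density
    ++nsteps; t += dt;
    if (thermostat && nsteps % rescale_every == 0 && !fr.empty()) {
      double ekf = 0;
      for (int i : fr) ekf += 0.5 * mass[i] *
        (V[3*i]*V[3*i] + V[3*i+1]*V[3*i+1] + V[3*i+2]*V[3*i+2]);
      ekf /= FCONV;
      double tmeas = 2.0 * ekf / (KB * 3.0 * fr.size());
      if (tmeas > 1e-9) {
        double fsc = std::sqrt(temperature / tmeas);
        for (int i : fr) for (int k=0;k<3;++k) V[3*i+k] *= fsc;
        etot_prev = epot + kinetic();
      }
      // light damping keeps the rigid group from accumulating drift
      if (has_rigid) for (int k=0;k<3;++k) { rv[k] *= 0.98; romega[k] *= 0.98; }
    }
    if (nsteps % 512 == 0) Rcpp::checkUserInterrupt();
  }

  double ek = kinetic();
  NumericMatrix xo(n,3), vo(n,3);
  for (int i=0;i<n;++i) for (int k=0;k<3;++k) { xo(i,k)=X[3*i+k]; vo(i,k)=V[3*i+k]; }
  return List::create(
    _["coords"] = xo, _["vel"] = vo, _["nsteps"] = nsteps,
    _["dt_final_fs"] = dt * 1e3, _["n_halvings"] = nhalve,
    _["epot"] = epot, _["ekin"] = ek,
    _["temperature"] = 2.0 * ek / (KB * ndof),
    _["failed"] = failed, _["time_ps"] = t);
}

// ---- map utilities --------------------------------------------------------

// Sum of per-atom isotropic Gaussians accumulated on a grid.
// [[Rcpp::export]]
NumericVector cpp_simulate_map(NumericMatrix coords, NumericVector weights,
                               IntegerVector dims, NumericVector origin,
                               double voxel, double sigma, double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid((R_xlen_t)nx * ny * nz);
  double inv2s2 = 1.0/(2.0*sigma*sigma), cut2 = cutoff*cutoff;
  int span = (int)std::ceil(cutoff / voxel);
  for (int a = 0; a < coords.nrow(); ++a) {
    double px = coords(a,0), py = coords(a,1), pz = coords(a,2), w = weights[a];
    int cx = (int)std::floor((px-origin[0])/voxel);
    int cy = (int)std::floor((py-origin[1])/voxel);
    int cz = (int)std::floor((pz-origin[2])/voxel);
    for (int iz = std::max(0,cz-span); iz <= std::min(nz-1,cz+span); ++iz)
    for (int iy = std::max(0,cy-span); iy <= std::min(ny-1,cy+span); ++iy)
    for (int ix = std::max(0,cx-span); ix <= std::min(nx-1,cx+span); ++ix) {
      double dx = origin[0]+ix*voxel-px;
      double dy = origin[1]+iy*voxel-py;
      double dz = origin[2]+iz*voxel-pz;
      double r2 = dx*dx+dy*dy+dz*dz;
      if (r2 > cut2) continue;
      grid[ix + (R_xlen_t)nx*(iy + (R_xlen_t)ny*iz)] += w * std::exp(-r2*inv2s2);
    }
  }
  return grid;
}

// CC (and optionally its coordinate gradient) of a structure's simulated
// density against a target map over the target-derived mask.
// [[Rcpp::export]]
List cpp_cc_grad(NumericMatrix coords, List mapspec, bool want_grad = false) {
  int n = coords.nrow();
  List spec = List::create(_["map"] = mapspec, _["k_map"] = 1.0,
                           _["map_sel"] = seq_len(n) - 1);
  Ctx c = build_ctx(spec, n);
  std::vector<double> X(3*n), G(3*n, 0.0);
  for (int i=0;i<n;++i) for (int k=0;k<3;++k) X[3*i+k] = coords(i,k);
  EnergyOut e = eval_energy(c, X.data(), G.data(), want_grad);
  double cc = 1.0 - e.map;    // k = 1
  List out = List::create(_["cc"] = cc);
  if (want_grad) {
    NumericMatrix gm(n,3);
    // gradient of E = 1-CC was accumulated; flip sign for dCC/dx
    for (int i=0;i<n;++i) for (int k=0;k<3;++k) gm(i,k) = -G[3*i+k];
    out["grad"] = gm;
  }
  return out;
}

static inline double trilinear(const std::vector<double>& g, int nx, int ny,
                               int nz, double fx, double fy, double fz) {
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx-1 || fy > ny-1 || fz > nz-1)
    return 0.0;
  int x0 = std::min((int)std::floor(fx), nx-2), x1 = x0+1;
  int y0 = std::min((int)std::floor(fy), ny-2), y1 = y0+1;
  int z0 = std::min((int)std::floor(fz), nz-2), z1 = z0+1;
  if (nx == 1) { x0 = x1 = 0; } if (ny == 1) { y0 = y1 = 0; }
  if (nz == 1) { z0 = z1 = 0; }
  double tx = fx-x0, ty = fy-y0, tz = fz-z0;
  auto at = [&](int i,int j,int k){ return g[i + (size_t)nx*(j + (size_t)ny*k)]; };
  double c00 = at(x0,y0,z0)*(1-tx) + at(x1,y0,z0)*tx;
  double c10 = at(x0,y1,z0)*(1-tx) + at(x1,y1,z0)*tx;
  double c01 = at(x0,y0,z1)*(1-tx) + at(x1,y0,z1)*tx;
  double c11 = at(x0,y1,z1)*(1-tx) + at(x1,y1,z1)*tx;
  double c0 = c00*(1-ty) + c10*ty, c1 = c01*(1-ty) + c11*ty;
  return c0*(1-tz) + c1*tz;
}

// Interpolated map values at arbitrary points (used for coarse dock scoring).
// [[Rcpp::export]]
NumericVector cpp_map_at(NumericVector grid, IntegerVector dims,
                         NumericVector origin, double voxel,
                         NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> g(grid.begin(), grid.end());
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double fx = (pts(i,0)-origin[0])/voxel;
    double fy = (pts(i,1)-origin[1])/voxel;
    double fz = (pts(i,2)-origin[2])/voxel;
    out[i] = trilinear(g, nx, ny, nz, fx, fy, fz);
  }
  return out;
}

// Coarse rigid docking scan: for each quaternion, slide the (centered) probe
// over a translation grid and record the mean interpolated density at the
// probe atoms; returns the best score and rotation index per translation.
// [[Rcpp::export]]
List cpp_coarse_dock(NumericVector grid, IntegerVector dims,
                     NumericVector origin, double voxel,
                     NumericMatrix probe, NumericMatrix quats,
                     NumericVector tr_origin, IntegerVector tr_dims,
                     double tr_step) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> g(grid.begin(), grid.end());
  int tnx = tr_dims[0], tny = tr_dims[1], tnz = tr_dims[2];
  size_t ntr = (size_t)tnx*tny*tnz;
  NumericVector best(ntr, R_NegInf);
  IntegerVector bestrot(ntr, -1);
  int na = probe.nrow();
  std::vector<double> rx(na), ry(na), rz(na);
  for (int q = 0; q < quats.nrow(); ++q) {
    double w = quats(q,0), x = quats(q,1), y = quats(q,2), z = quats(q,3);
    double R11 = 1-2*(y*y+z*z), R12 = 2*(x*y-w*z), R13 = 2*(x*z+w*y);
    double R21 = 2*(x*y+w*z), R22 = 1-2*(x*x+z*z), R23 = 2*(y*z-w*x);
    double R31 = 2*(x*z-w*y), R32 = 2*(y*z+w*x), R33 = 1-2*(x*x+y*y);
    for (int a = 0; a < na; ++a) {
      double px = probe(a,0), py = probe(a,1), pz = probe(a,2);
      rx[a] = R11*px + R12*py + R13*pz;
      ry[a] = R21*px + R22*py + R23*pz;
      rz[a] = R31*px + R32*py + R33*pz;
    }
    size_t ti = 0;
    for (int kz = 0; kz < tnz; ++kz)
    for (int ky = 0; ky < tny; ++ky)
    for (int kx = 0; kx < tnx; ++kx, ++ti) {
      double tx = tr_origin[0] + kx*tr_step;
      double ty = tr_origin[1] + ky*tr_step;
      double tz = tr_origin[2] + kz*tr_step;
      double s = 0;
      for (int a = 0; a < na; ++a) {
        double fx = (rx[a]+tx-origin[0])/voxel;
        double fy = (ry[a]+ty-origin[1])/voxel;
        double fz = (rz[a]+tz-origin[2])/voxel;
        s += trilinear(g, nx, ny, nz, fx, fy, fz);
      }
      s /= na;
      if (s > best[ti]) { best[ti] = s; bestrot[ti] = q; }
    }
    if (q % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = best, _["rot"] = bestrot);
}
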