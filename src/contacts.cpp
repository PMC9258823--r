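#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double min_image_d2(double dx, double dy, double dz,
                                  double bx, double by, double bz) {
  dx -= bx * std::round(dx / bx);
  dy -= by * std::round(dy / by);
  dz -= bz * std::round(dz / bz);
  return dx * dx + dy * dy + dz * dz;
}

// Per-frame binary residue x group contact counting.
// Each lipid bead carries a bitmask of the groups it belongs to; a residue
// contacts a group in a frame if any of its beads lies within `cutoff`
// (minimum image) of any bead carrying that group's bit. Uses a cell list
// over lipid beads when the box allows (>= 3 cells per axis), otherwise an
// exact all-pairs sweep; both paths give identical results.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_counts(List frames, NumericMatrix boxes,
                                 IntegerVector protein_idx,
                                 IntegerVector protein_res,
                                 IntegerVector lipid_idx,
                                 IntegerVector lipid_mask,
                                 int n_res, int n_groups, double cutoff) {
  const int nf = frames.size();
  const int np = protein_idx.size();
  const int nl = lipid_idx.size();
  const double cut2 = cutoff * cutoff;
  const int full_mask = (n_groups >= 31) ? ~0 : ((1 << n_groups) - 1);
  IntegerMatrix counts(n_res, n_groups);
  std::vector<int> resmask(n_res);

  std::vector<int> cell_head, cell_next(nl);

  for (int f = 0; f < nf; ++f) {
    NumericMatrix xyz = frames[f];
    const double bx = boxes(f, 0), by = boxes(f, 1), bz = boxes(f, 2);
    std::fill(resmask.begin(), resmask.end(), 0);

    int ncx = (int)std::floor(bx / cutoff);
    int ncy = (int)std::floor(by / cutoff);
    int ncz = (int)std::floor(bz / cutoff);

    if (ncx >= 3 && ncy >= 3 && ncz >= 3 && nl > 0) {
      // cell list over lipid beads
      const double lx = bx / ncx, ly = by / ncy, lz = bz / ncz;
      const int ncells = ncx * ncy * ncz;
      cell_head.assign(ncells, -1);
      for (int j = 0; j < nl; ++j) {
        const int l = lipid_idx[j];
        double x = std::fmod(xyz(l, 0), bx); if (x < 0) x += bx;
        double y = std::fmod(xyz(l, 1), by); if (y < 0) y += by;
        double z = std::fmod(xyz(l, 2), bz); if (z < 0) z += bz;
        int cx = (int)(x / lx); if (cx >= ncx) cx = ncx - 1;
        int cy = (int)(y / ly); if (cy >= ncy) cy = ncy - 1;
        int cz = (int)(z / lz); if (cz >= ncz) cz = ncz - 1;
        const int c = (cz * ncy + cy) * ncx + cx;
        cell_next[j] = cell_head[c];
        cell_head[c] = j;
      }
      for (int i = 0; i < np; ++i) {
        const int r = protein_res[i];
        if (resmask[r] == full_mask) continue;
        const int p = protein_idx[i];
        const double px = xyz(p, 0), py = xyz(p, 1), pz = xyz(p, 2);
        double wx = std::fmod(px, bx); if (wx < 0) wx += bx;
        double wy = std::fmod(py, by); if (wy < 0) wy += by;
        double wz = std::fmod(pz, bz); if (wz < 0) wz += bz;
        int cx = (int)(wx / lx); if (cx >= ncx) cx = ncx - 1;
        int cy = (int)(wy / ly); if (cy >= ncy) cy = ncy - 1;
        int cz = (int)(wz / lz); if (cz >= ncz) cz = ncz - 1;
        for (int dz = -1; dz <= 1; ++dz) {
          int zc = (cz + dz + ncz) % ncz;
          for (int dy = -1; dy <= 1; ++dy) {
            int yc = (cy + dy + ncy) % ncy;
            for (int dx = -1; dx <= 1; ++dx) {
              int xc = (cx + dx + ncx) % ncx;
              for (int j = cell_head[(zc * ncy + yc) * ncx + xc]; j >= 0;
                   j = cell_next[j]) {
                const int m = lipid_mask[j];
                if ((resmask[r] & m) == m) continue;
                const int l = lipid_idx[j];
                if (min_image_d2(px - xyz(l, 0), py - xyz(l, 1),
                                 pz - xyz(l, 2), bx, by, bz) <= cut2)
                  resmask[r] |= m;
              }
            }
          }
        }
      }
    } else {
      // exact all-pairs fallback for small boxes
      for (int i = 0; i < np; ++i) {
        const int r = protein_res[i];
        if (resmask[r] == full_mask) continue;
        const int p = protein_idx[i];
        const double px = xyz(p, 0), py = xyz(p, 1), pz = xyz(p, 2);
        for (int j = 0; j < nl; ++j) {
          const int m = lipid_mask[j];
          if ((resmask[r] & m) == m) continue;
          const int l = lipid_idx[j];
          if (min_image_d2(px - xyz(l, 0), py - xyz(l, 1), pz - xyz(l, 2),
                           bx, by, bz) <= cut2)
            resmask[r] |= m;
        }
      }
    }

    for (int r = 0; r < n_res; ++r) {
      int m = resmask[r];
      if (!m) continue;
      for (int g = 0; g < n_groups; ++g)
        if (m & (1 << g)) counts(r, g) += 1;
    }
  }
  return counts;
}

// Per-frame count of tagged beads (e.g. PIP PO4 particles) lying within
// `cutoff` (minimum image) of any protein bead.
// [[Rcpp::export]]
IntegerVector cpp_within_counts(List frames, NumericMatrix boxes,
                                IntegerVector protein_idx,
                                IntegerVector target_idx, double cutoff) {
  const int nf = frames.size();
  const int np = protein_idx.size();
  const int nt = target_idx.size();
  const double cut2 = cutoff * cutoff;
  IntegerVector out(nf);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix xyz = frames[f];
    const double bx = boxes(f, 0), by = boxes(f, 1), bz = boxes(f, 2);
    int count = 0;
    for (int j = 0; j < nt; ++j) {
      const int t = target_idx[j];
      const double tx = xyz(t, 0), ty = xyz(t, 1), tz = xyz(t, 2);
      for (int i = 0; i < np; ++i) {
        const int p = protein_idx[i];
        if (min_image_d2(tx - xyz(p, 0), ty - xyz(p, 1), tz - xyz(p, 2),
                         bx, by, bz) <= cut2) {
          ++count;
          break;
        }
      }
    }
    out[f] = count;
  }
  return out;
}
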