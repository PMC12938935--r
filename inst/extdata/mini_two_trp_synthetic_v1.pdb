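HEADER    SYNTHETIC TEST FIXTURE
REMARK    two tryptophan residues, synthetic coordinates
ATOM      1  N   TRP A  10      -2.400   1.200   0.500  1.00  0.00           N
ATOM      2  CA  TRP A  10      -1.500   0.400  -0.300  1.00  0.00           C
ATOM      3  CB  TRP A  10      -0.900  -0.800   0.400  1.00  0.00           C
ATOM      4  CG  TRP A  10       0.000   0.000   0.000  1.00  0.00           C
ATOM      5  CD1 TRP A  10       1.090   0.840   0.000  1.00  0.00           C
ATOM      6  NE1 TRP A  10       2.230   0.100   0.000  1.00  0.00           N
ATOM      7  CE2 TRP A  10       1.910  -1.230   0.000  1.00  0.00           C
ATOM      8  CD2 TRP A  10       0.520  -1.340   0.000  1.00  0.00           C
ATOM      9  CE3 TRP A  10      -0.270  -2.500   0.000  1.00  0.00           C
ATOM     10  CZ3 TRP A  10       0.340  -3.720   0.000  1.00  0.00           C
ATOM     11  CH2 TRP A  10       1.720  -3.800   0.000  1.00  0.00           C
ATOM     12  CZ2 TRP A  10       2.530  -2.680   0.000  1.00  0.00           C
ATOM     13  N   TRP A  25       9.600   6.200   8.500  1.00  0.00           N
ATOM     14  CA  TRP A  25      10.500   5.400   7.700  1.00  0.00           C
ATOM     15  CB  TRP A  25      11.100   4.200   8.400  1.00  0.00           C
ATOM     16  CG  TRP A  25      12.000   5.000   8.000  1.00  0.00           C
ATOM     17  CD1 TRP A  25      13.090   5.840   8.000  1.00  0.00           C
ATOM     18  NE1 TRP A  25      14.230   5.100   8.000  1.00  0.00           N
ATOM     19  CE2 TRP A  25      13.910   3.770   8.000  1.00  0.00           C
ATOM     20  CD2 TRP A  25      12.520   3.660   8.000  1.00  0.00           C
ATOM     21  CE3 TRP A  25      11.730   2.500   8.000  1.00  0.00           C
ATOM     22  CZ3 TRP A  25      12.340   1.280   8.000  1.00  0.00           C
ATOM     23  CH2 TRP A  25      13.720   1.200   8.000  1.00  0.00           C
ATOM     24  CZ2 TRP A  25      14.530   2.320   8.000  1.00  0.00           C
END
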