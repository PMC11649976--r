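name: CYP2J2
units: ring_size
width_gauge: 1.5
facial_depth: 0.0
rear_depth: 1.5
heme_access: rear
cells:
  A:
  - 0
  - 0
  B:
  - 1
  - 0
  C:
  - 2
  - 0
  D:
  - 0
  - 1
  E:
  - -1
  - 0
  F:
  - -2
  - 1
  G:
  - -1
  - 1
  H:
  - 1
  - 1
  I:
  - 2
  - 1
  J:
  - 0
  - 2
  K:
  - -1
  - 2
  L:
  - -2
  - 2
  M:
  - -3
  - 3
  'N':
  - -2
  - 3
  O:
  - -1
  - 3
  P:
  - -1
  - 4
  Q:
  - -2
  - 4
  R:
  - -3
  - 4
  S:
  - -4
  - 5
  T:
  - -3
  - 5
  U:
  - -2
  - 5
  eB:
  - 3
  - 0
  eC:
  - 3
  - 1
  eE:
  - -2
  - 0
  eJ:
  - 1
  - 2
  eL:
  - -3
  - 2
  eO:
  - 0
  - 3
  eP:
  - 0
  - 4
  eR:
  - -4
  - 4
  eU:
  - -1
  - 5
positions:
  '1':
  - -2
  - -2
  '2':
  - 0
  - -2
  '3':
  - 2
  - -2
  '4':
  - 4
  - -2
  '5':
  - -3
  - -1
  '6':
  - -1
  - -1
  '7':
  - 1
  - -1
  '8':
  - 3
  - -1
  '9':
  - 5
  - -1
  '10':
  - -1
  - 1
  '11':
  - 1
  - 1
  '12':
  - 3
  - 1
  '13':
  - 5
  - 1
  '14':
  - -4
  - 2
  '15':
  - -2
  - 2
  '16':
  - 0
  - 2
  '17':
  - 2
  - 2
  '18':
  - 4
  - 2
  '19':
  - 6
  - 2
  '20':
  - -4
  - 4
  '21':
  - -2
  - 4
  '22':
  - 0
  - 4
  '23':
  - 2
  - 4
  '24':
  - 4
  - 4
  '25':
  - 6
  - 4
  '26':
  - -3
  - 5
  '27':
  - -1
  - 5
  '28':
  - 1
  - 5
  '29':
  - 3
  - 5
  '30':
  - 5
  - 5
  '31':
  - -3
  - 7
  '32':
  - -1
  - 7
  '33':
  - 1
  - 7
  '34':
  - 3
  - 7
  '35':
  - -4
  - 8
  '36':
  - -2
  - 8
  '37':
  - 0
  - 8
  '38':
  - 2
  - 8
  '39':
  - -4
  - 10
  '40':
  - -2
  - 10
  '41':
  - 0
  - 10
  '42':
  - 2
  - 10
  '43':
  - -3
  - 11
  '44':
  - -1
  - 11
  '45':
  - 1
  - 11
  '46':
  - 3
  - 11
  '47':
  - -3
  - 13
  '48':
  - -1
  - 13
  '49':
  - 1
  - 13
  '50':
  - 3
  - 13
  '51':
  - -4
  - 14
  '52':
  - -2
  - 14
  '53':
  - 0
  - 14
  '54':
  - 2
  - 14
  11':
  - -3
  - 1
  48':
  - 2
  - 16
  49':
  - 1
  - 17
  50':
  - 0
  - 16
  51':
  - -1
  - 17
  52':
  - -2
  - 16
  53':
  - -3
  - 17
  54':
  - -4
  - 16
  eB.3:
  - 7
  - 1
  eB.4:
  - 7
  - -1
  eB.5:
  - 6
  - -2
  eC.2:
  - 7
  - 5
  eC.3:
  - 8
  - 4
  eC.4:
  - 8
  - 2
  eE.1:
  - -5
  - 1
  eE.5:
  - -4
  - -2
  eE.6:
  - -5
  - -1
  eJ.2:
  - 4
  - 8
  eJ.3:
  - 5
  - 7
  eL.1:
  - -5
  - 7
  eL.6:
  - -5
  - 5
  eO.3:
  - 4
  - 10
  eP.2:
  - 4
  - 14
  eP.3:
  - 5
  - 13
  eP.4:
  - 5
  - 11
  eR.1:
  - -5
  - 13
  eR.6:
  - -5
  - 11
  eU.2:
  - 3
  - 17
  eU.3:
  - 4
  - 16
rings:
  A:
  - '10'
  - '16'
  - '11'
  - '7'
  - '2'
  - '6'
  B:
  - '11'
  - '17'
  - '12'
  - '8'
  - '3'
  - '7'
  C:
  - '12'
  - '18'
  - '13'
  - '9'
  - '4'
  - '8'
  D:
  - '22'
  - '28'
  - '23'
  - '17'
  - '11'
  - '16'
  E:
  - 11'
  - '15'
  - '10'
  - '6'
  - '1'
  - '5'
  F:
  - '20'
  - '26'
  - '21'
  - '15'
  - 11'
  - '14'
  G:
  - '21'
  - '27'
  - '22'
  - '16'
  - '10'
  - '15'
  H:
  - '23'
  - '29'
  - '24'
  - '18'
  - '12'
  - '17'
  I:
  - '24'
  - '30'
  - '25'
  - '19'
  - '13'
  - '18'
  J:
  - '33'
  - '38'
  - '34'
  - '29'
  - '23'
  - '28'
  K:
  - '32'
  - '37'
  - '33'
  - '28'
  - '22'
  - '27'
  L:
  - '31'
  - '36'
  - '32'
  - '27'
  - '21'
  - '26'
  M:
  - '39'
  - '43'
  - '40'
  - '36'
  - '31'
  - '35'
  'N':
  - '40'
  - '44'
  - '41'
  - '37'
  - '32'
  - '36'
  O:
  - '41'
  - '45'
  - '42'
  - '38'
  - '33'
  - '37'
  P:
  - '49'
  - '54'
  - '50'
  - '46'
  - '42'
  - '45'
  Q:
  - '48'
  - '53'
  - '49'
  - '45'
  - '41'
  - '44'
  R:
  - '47'
  - '52'
  - '48'
  - '44'
  - '40'
  - '43'
  S:
  - 54'
  - 53'
  - 52'
  - '52'
  - '47'
  - '51'
  T:
  - 52'
  - 51'
  - 50'
  - '53'
  - '48'
  - '52'
  U:
  - 50'
  - 49'
  - 48'
  - '54'
  - '49'
  - '53'
  eB:
  - '13'
  - '19'
  - eB.3
  - eB.4
  - eB.5
  - '9'
  eC:
  - '25'
  - eC.2
  - eC.3
  - eC.4
  - eB.3
  - '19'
  eE:
  - eE.1
  - '14'
  - 11'
  - '5'
  - eE.5
  - eE.6
  eJ:
  - '34'
  - eJ.2
  - eJ.3
  - '30'
  - '24'
  - '29'
  eL:
  - eL.1
  - '35'
  - '31'
  - '26'
  - '20'
  - eL.6
  eO:
  - '42'
  - '46'
  - eO.3
  - eJ.2
  - '34'
  - '38'
  eP:
  - '50'
  - eP.2
  - eP.3
  - eP.4
  - eO.3
  - '46'
  eR:
  - eR.1
  - '51'
  - '47'
  - '43'
  - '39'
  - eR.6
  eU:
  - 48'
  - eU.2
  - eU.3
  - eP.2
  - '50'
  - '54'
site_of_oxidation:
- '2'
- '3'
- '4'
shelf:
  edge:
  - eE.1
  - 11'
  - '10'
  barrier:
    kx_max: -3
    ky_level: 1
under_shelf:
- eE.5
- eE.6
left_end:
- 11'
- '14'
- '20'
- eL.6
- eL.1
- '35'
- '39'
- eR.6
- eR.1
- '51'
- 54'
entrance:
- 49'
- 54'
trigger:
  path:
  - eB
  - C
  - B
  pillar:
  - 0.5
  - 0.5
  - 3.0
  support_rings:
  - K
  - J
  - O
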