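{
  "language": "en",
  "menu": {
    "prompt": "Hi, I'm Wakamola {emoji:wave}! What would you like to do?\n1. Personal\n2. Diet\n3. Activity\n4. Wakanet (share with your contacts)\n5. Wakastatus (your scores)\n6. About\nAnswer with a number 1-6."
  },
  "strings": {
    "invalid_choice": "I didn't understand that. Please answer with one of the listed options.",
    "invalid_number": "Please answer with a number between {min} and {max}.",
    "invalid_boolean": "Please answer yes or no.",
    "section_complete": "Great, the {section} section is complete! {emoji:party}",
    "already_complete": "You already completed that section. Restart it explicitly if you want to change your answers.",
    "assessment_complete": "You have completed all sections. Check your Wakastatus from the menu!",
    "not_ready": "Complete the Personal, Diet and Activity sections first."
  },
  "sections": {
    "personal": {
      "title": "Personal",
      "questions": {
        "weight": { "prompt": "What is your weight in kilograms?" },
        "height": { "prompt": "What is your height in metres (e.g. 1.75)?" },
        "gender": { "prompt": "What is your gender? (female / male / other)" },
        "age": { "prompt": "How old are you?" },
        "education_level": { "prompt": "What is your highest education level? (primary / secondary / university / postgraduate)" },
        "marital_status": { "prompt": "What is your marital status? (single / partner / married / other)" },
        "household_size": { "prompt": "How many people live at your home, including you?" },
        "main_activity": { "prompt": "What is your main activity? (study / work / other)" },
        "zip_code": { "prompt": "What is your zip code?" },
        "sleep_hours": { "prompt": "How many hours per day do you sleep?" },
        "cigarettes": { "prompt": "How many cigarettes do you smoke per day?" },
        "dx_hypertension": { "prompt": "Have you ever been diagnosed with (or take medication for) hypertension? (yes/no)" },
        "dx_diabetes": { "prompt": "Have you ever been diagnosed with (or take medication for) diabetes? (yes/no)" },
        "dx_cholesterol": { "prompt": "Have you ever been diagnosed with (or take medication for) high cholesterol? (yes/no)" },
        "dx_cardiovascular": { "prompt": "Have you ever been diagnosed with (or take medication for) cardiovascular disease? (yes/no)" }
      }
    },
    "diet": {
      "title": "Diet",
      "item_prompt": "How often do you consume {item}? {emoji:apple}\n1. Never\n2. Less than once a week\n3. 1-2 times a week\n4. 3-6 times a week\n5. Once a day\n6. Twice a day or more",
      "reprompt": "Please answer with a number from 1 to 6."
    },
    "activity": {
      "title": "Activity",
      "questions": {
        "vigorous_days": { "prompt": "In the last 7 days, on how many days did you do vigorous physical activity? (0-7)" },
        "vigorous_minutes": { "prompt": "How many minutes did you usually spend doing vigorous activity on one of those days?" },
        "moderate_days": { "prompt": "In the last 7 days, on how many days did you do moderate physical activity? (0-7)" },
        "moderate_minutes": { "prompt": "How many minutes did you usually spend doing moderate activity on one of those days?" },
        "walk_days": { "prompt": "In the last 7 days, on how many days did you walk for at least 10 minutes at a time? (0-7)" },
        "walk_minutes": { "prompt": "How many minutes did you usually spend walking on one of those days?" },
        "sitting_hours": { "prompt": "How many hours per week do you spend sitting?" }
      }
    },
    "wakanet": {
      "title": "Wakanet",
      "intro": "Share Wakamola with your contacts to build your network {emoji:muscle}. You have {n_contacts} contacts.",
      "invite_messages": {
        "home": "Join me on Wakamola! Invitation for the people I live with: {token}",
        "family": "Join me on Wakamola! Invitation for my family: {token}",
        "friend": "Join me on Wakamola! Invitation for my friends: {token}",
        "work": "Join me on Wakamola! Invitation for my work colleagues: {token}"
      }
    },
    "wakastatus": {
      "title": "Wakastatus",
      "status_message": "Here is your status {emoji:smile}\nWakastatus: {wakastatus}/100\nDiet (Wakalimentation): {diet_score}\nActivity: {activity_score}\nWakaBMI: {bmi_score}\nSocial network (Wakasocial): {social_score}\nBMI category: {bmi_category}\nThe higher the better - goal 100!"
    },
    "about": {
      "title": "About",
      "text": "Wakamola helps you assess your diet, physical activity, BMI and social network, and gives you a global status score from 0 to 100."
    }
  },
  "emoji": {
    "wave": "👋",
    "party": "🎉",
    "apple": "🍎",
    "muscle": "💪",
    "smile": "🙂"
  }
}
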